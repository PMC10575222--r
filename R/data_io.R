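#' Single-seed hyperspectral cube
#'
#' A `seed_cube` wraps one seed's reflectance cube (rows x cols x bands,
#' band axis last) together with its variety label, domain (harvest season)
#' and labelling status. Reflectance is stored as floating point, typically
#' in \[0, ~1.5\]. The canonical geometry used for single wheat seeds is
#' 60 x 80 pixels by 94 bands (400--1000 nm); smaller crops are brought to
#' canonical size with [canonicalize()].
#'
#' @param values numeric 3-D array, rows x cols x bands.
#' @param variety integer class index in `0..C-1`, or `NA` for an unknown
#'   (unlabeled) variety.
#' @param domain `"source"` or `"target"`.
#' @param labeled logical; if `TRUE`, `variety` must be a valid class index.
#' @param sample_id unique sample identifier string.
#' @return An object of class `seed_cube`.
#' @examples
#' x <- seed_cube(array(0.5, c(4, 5, 3)), variety = 0L, domain = "source",
#'                sample_id = "s1")
#' dim(x$values)
#' @export
seed_cube <- function(values, variety = NA_integer_, domain = c("source", "target"),
                      labeled = !is.na(variety), sample_id = "seed") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array (rows x cols x bands).")
  }
  domain <- match.arg(tolower(domain), c("source", "target"))
  variety <- suppressWarnings(as.integer(variety))
  if (isTRUE(labeled) && (is.na(variety) || variety < 0L)) {
    abort("A labeled seed cube needs a valid non-negative variety index.")
  }
  structure(
    list(values = values, variety = variety, domain = domain,
         labeled = isTRUE(labeled), sample_id = as.character(sample_id)),
    class = "seed_cube"
  )
}

#' @export
print.seed_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<seed_cube %s: %d x %d px, %d bands, domain=%s, variety=%s%s>\n",
              x$sample_id, d[1], d[2], d[3], x$domain,
              ifelse(is.na(x$variety), "?", x$variety),
              if (x$labeled) "" else " (unlabeled)"))
  invisible(x)
}

#' Zero-pad a seed cube to canonical spatial size
#'
#' Pads the spatial support of a cropped seed with zeros so that every cube
#' shares one geometry (default 60 x 80 pixels), as required before batching
#' cubes into a network. The seed is centred in the padded frame (odd margins
#' split by floor division); the band axis is untouched, added pixels are
#' exactly zero, and the total reflectance sum is conserved. The operation is
#' idempotent: a cube already at target size is returned unchanged.
#'
#' @param cube a [seed_cube()].
#' @param target_shape integer 2-vector `(rows, cols)`; default `c(60, 80)`.
#' @return A `seed_cube` with spatial shape `target_shape`.
#' @export
canonicalize <- function(cube, target_shape = c(60L, 80L)) {
  stopifnot(inherits(cube, "seed_cube"))
  d <- dim(cube$values)
  tr <- as.integer(target_shape[1]); tc <- as.integer(target_shape[2])
  if (d[1] > tr || d[2] > tc) {
    abort(sprintf(
      "Cube %s is %d x %d px, larger than the %d x %d target frame.",
      cube$sample_id, d[1], d[2], tr, tc), class = "adfs_geometry_error")
  }
  if (d[1] == tr && d[2] == tc) return(cube)
  out <- array(0, c(tr, tc, d[3]))
  r0 <- (tr - d[1]) %/% 2L
  c0 <- (tc - d[2]) %/% 2L
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- cube$values
  cube$values <- out
  cube
}

# ---- cube file I/O ---------------------------------------------------------

#' Read or write a hyperspectral seed cube
#'
#' Two on-disk dialects are supported: `"envi"` (a plain-text ENVI header next
#' to a raw binary in BSQ, BIL or BIP interleave, 32-bit little-endian float)
#' and `"rds"` (a serialized R array). Values are returned as a numeric array
#' with the band axis last; no canonicalization is applied on read.
#'
#' @param path file path. For ENVI, `path` is the binary file and the header
#'   is `<path>.hdr`.
#' @param dialect `"envi"` or `"rds"`.
#' @param n_bands optional expected band count; a mismatch raises a geometry
#'   error (used to enforce a manifest's band count).
#' @param ... metadata passed to [seed_cube()] (`variety`, `domain`,
#'   `labeled`, `sample_id`).
#' @return `read_cube()` returns a [seed_cube()]; `write_cube()` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path, dialect = c("envi", "rds"), n_bands = NULL, ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Cube file not found: %s", path), class = "adfs_format_error")
  }
  values <- switch(dialect,
    rds = {
      v <- tryCatch(readRDS(path), error = function(e) {
        abort(sprintf("Not a readable RDS array archive: %s", path),
              class = "adfs_format_error")
      })
      if (!is.array(v) || length(dim(v)) != 3L) {
        abort(sprintf("RDS archive %s does not hold a 3-D array.", path),
              class = "adfs_format_error")
      }
      v
    },
    envi = read_envi_cube(path)
  )
  if (!is.null(n_bands) && dim(values)[3] != n_bands) {
    abort(sprintf("Cube %s has %d bands but %d were expected.",
                  path, dim(values)[3], n_bands),
          class = "adfs_geometry_error")
  }
  meta <- list(...)
  if (is.null(meta$sample_id)) {
    meta$sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  do.call(seed_cube, c(list(values = values), meta))
}

#' @rdname read_cube
#' @param cube a [seed_cube()] to write.
#' @param interleave ENVI interleave to write: `"bsq"`, `"bil"` or `"bip"`.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "rds"),
                       interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "seed_cube"))
  dialect <- match.arg(dialect)
  if (dialect == "rds") {
    saveRDS(cube$values, path)
  } else {
    write_envi_cube(cube$values, path, match.arg(interleave))
  }
  invisible(path)
}

# ENVI: `lines` = rows, `samples` = cols. Only data type 4 (float32) and
# byte order 0 (little endian) are produced/consumed; that covers reflectance
# cubes exported by the common conversion tools.
read_envi_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    abort(sprintf("ENVI header missing: %s", hdr_path), class = "adfs_format_error")
  }
  lines_raw <- readLines(hdr_path, warn = FALSE)
  field <- function(name) {
    hit <- grep(sprintf("^\\s*%s\\s*=", name), tolower(lines_raw))
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", lines_raw[hit[1]]))
  }
  nr <- as.integer(field("lines")); nc <- as.integer(field("samples"))
  nb <- as.integer(field("bands"))
  itl <- tolower(field("interleave") %||% "bsq")
  dtype <- as.integer(field("data type") %||% "4")
  if (any(is.na(c(nr, nc, nb)))) {
    abort(sprintf("ENVI header %s lacks lines/samples/bands.", hdr_path),
          class = "adfs_format_error")
  }
  if (dtype != 4L) {
    abort(sprintf("ENVI data type %d unsupported (only 4 = float32).", dtype),
          class = "adfs_format_error")
  }
  n <- nr * nc * nb
  raw_vals <- readBin(path, what = "numeric", n = n, size = 4L,
                      endian = "little")
  if (length(raw_vals) != n) {
    abort(sprintf("ENVI binary %s holds %d values, expected %d.",
                  path, length(raw_vals), n), class = "adfs_format_error")
  }
  # fastest-varying axis first, per interleave
  switch(itl,
    bsq = aperm(array(raw_vals, c(nc, nr, nb)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, c(nc, nb, nr)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, c(nb, nc, nr)), c(3, 2, 1)),
    abort(sprintf("Unknown ENVI interleave '%s'.", itl),
          class = "adfs_format_error")
  )
}

write_envi_cube <- function(values, path, interleave = "bsq") {
  d <- dim(values)
  ordered <- switch(interleave,
    bsq = aperm(values, c(2, 1, 3)),
    bil = aperm(values, c(2, 3, 1)),
    bip = aperm(values, c(3, 2, 1))
  )
  writeBin(as.numeric(ordered), path, size = 4L, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0")
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# ---- manifest --------------------------------------------------------------

#' Load a dataset manifest
#'
#' A manifest is a CSV with columns `path, sample_id, variety, domain,
#' labeled` cataloguing the cube files of a two-season experiment. Class
#' names are inferred from the `variety` column in first-appearance order;
#' unlabeled rows may leave `variety` empty. Domains must be
#' `source`/`target` (case-insensitive).
#'
#' @param path CSV file path.
#' @param band_count optional expected band count recorded on the manifest
#'   and enforced when cubes are read.
#' @return A tibble of class `dataset_manifest` with columns `path,
#'   sample_id, variety (class name), variety_index, domain, labeled`, and
#'   attributes `class_names` and `band_count`.
#' @export
load_manifest <- function(path, band_count = NULL) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Cannot read manifest CSV %s: %s",
                                      path, conditionMessage(e)),
                              class = "adfs_manifest_error"))
  as_manifest(df, band_count = band_count)
}

#' @rdname load_manifest
#' @param df a data frame with the manifest columns (in-memory alternative
#'   to reading a CSV).
#' @export
as_manifest <- function(df, band_count = NULL) {
  need <- c("sample_id", "variety", "domain", "labeled")
  if (nrow(df) == 0L) {
    abort("Manifest is empty.", class = "adfs_manifest_error")
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Manifest lacks columns: %s", paste(missing_cols, collapse = ", ")),
          class = "adfs_manifest_error")
  }
  df <- as_tibble(df)
  if (!"path" %in% names(df)) df$path <- NA_character_
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    abort(sprintf("Duplicate sample_id in manifest: %s", dup),
          class = "adfs_manifest_error")
  }
  dom <- tolower(as.character(df$domain))
  bad <- setdiff(unique(dom), c("source", "target"))
  if (length(bad)) {
    abort(sprintf("Unknown domain token(s): %s", paste(bad, collapse = ", ")),
          class = "adfs_manifest_error")
  }
  df$domain <- dom
  df$labeled <- as.logical(df$labeled)
  vchr <- as.character(df$variety)
  vchr[!is.na(vchr) & vchr %in% c("", "UNKNOWN", "NA")] <- NA_character_
  class_names <- unique(vchr[!is.na(vchr)])
  df$variety <- vchr
  df$variety_index <- match(vchr, class_names) - 1L
  if (any(df$labeled & is.na(df$variety_index))) {
    abort("Labeled manifest rows must carry a variety.",
          class = "adfs_manifest_error")
  }
  df <- df[, c("path", "sample_id", "variety", "variety_index", "domain", "labeled")]
  structure(df, class = c("dataset_manifest", class(df)),
            class_names = class_names, band_count = band_count)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d samples, %d classes (%s), bands=%s>\n",
              nrow(x), length(attr(x, "class_names")),
              paste(attr(x, "class_names"), collapse = ", "),
              attr(x, "band_count") %||% "?"))
  NextMethod()
}

#' Bundle seed cubes with their manifest
#'
#' A `cube_set` is the in-memory dataset handle used by the training and
#' evaluation functions: a named list of [seed_cube()]s plus a
#' [as_manifest()] tibble describing them.
#'
#' @param cubes list of `seed_cube`s.
#' @param class_names optional class names giving the meaning of variety
#'   indices; defaults to `class_0 .. class_{C-1}` over the observed indices.
#' @return An object of class `cube_set` with elements `cubes` (named list)
#'   and `manifest`.
#' @export
cube_set <- function(cubes, class_names = NULL) {
  stopifnot(length(cubes) > 0L, all(vapply(cubes, inherits, TRUE, "seed_cube")))
  ids <- vapply(cubes, `[[`, "", "sample_id")
  names(cubes) <- ids
  vidx <- vapply(cubes, `[[`, 1L, "variety")
  if (is.null(class_names)) {
    cmax <- suppressWarnings(max(vidx, na.rm = TRUE))
    class_names <- paste0("class_", seq_len(cmax + 1L) - 1L)
  }
  man <- as_manifest(tibble(
    sample_id = ids,
    variety = ifelse(is.na(vidx), NA_character_, class_names[vidx + 1L]),
    domain = vapply(cubes, `[[`, "", "domain"),
    labeled = vapply(cubes, `[[`, TRUE, "labeled")
  ), band_count = dim(cubes[[1]]$values)[3])
  attr(man, "class_names") <- class_names
  structure(list(cubes = cubes, manifest = man), class = "cube_set")
}

#' @export
print.cube_set <- function(x, ...) {
  d <- dim(x$cubes[[1]]$values)
  cat(sprintf("<cube_set: %d cubes of %d x %d x %d>\n",
              length(x$cubes), d[1], d[2], d[3]))
  print(x$manifest)
  invisible(x)
}

#' Read all cubes listed in a manifest
#'
#' @param manifest a [load_manifest()] result with valid `path`s.
#' @param dialect cube file dialect, see [read_cube()].
#' @param target_shape if non-NULL, every cube is [canonicalize()]d to this
#'   spatial shape after reading.
#' @return A [cube_set()].
#' @export
load_cube_set <- function(manifest, dialect = c("envi", "rds"),
                          target_shape = NULL) {
  dialect <- match.arg(dialect)
  nb <- attr(manifest, "band_count")
  cubes <- purrr::pmap(
    list(manifest$path, manifest$sample_id, manifest$variety_index,
         manifest$domain, manifest$labeled),
    function(p, id, v, dom, lab) {
      cb <- read_cube(p, dialect = dialect, n_bands = nb, sample_id = id,
                      variety = v, domain = dom, labeled = lab)
      if (!is.null(target_shape)) cb <- canonicalize(cb, target_shape) else cb
      cb
    })
  cube_set(cubes, class_names = attr(manifest, "class_names"))
}

# ---- batching / standardization -------------------------------------------

#' Per-band standardization statistics
#'
#' Computes the per-band mean and standard deviation over all pixels of the
#' given cubes. To avoid information leaking from held-out partitions, fit
#' these on the source training ids only and reuse them everywhere else.
#'
#' @param data a [cube_set()].
#' @param ids sample ids to pool (default: all).
#' @return A list with numeric vectors `mean` and `sd` (length = bands).
#' @export
fit_band_stats <- function(data, ids = NULL) {
  ids <- ids %||% names(data$cubes)
  nb <- dim(data$cubes[[1]]$values)[3]
  s <- numeric(nb); ss <- numeric(nb); n <- 0
  for (id in ids) {
    v <- data$cubes[[id]]$values
    m <- matrix(v, ncol = nb)
    s <- s + colSums(m)
    ss <- ss + colSums(m^2)
    n <- n + nrow(m)
  }
  mu <- s / n
  sd <- sqrt(pmax(ss / n - mu^2, 0))
  sd[sd < 1e-8] <- 1
  list(mean = mu, sd = sd)
}

# Stack cubes into an (H, W, B, N) array, standardized per band.
assemble_batch <- function(data, ids, stats = NULL) {
  d <- dim(data$cubes[[ids[1]]]$values)
  out <- array(0, c(d, length(ids)))
  for (i in seq_along(ids)) {
    v <- data$cubes[[ids[i]]]$values
    if (!all(dim(v) == d)) {
      abort(sprintf("Cube %s is %s, expected %s; canonicalize first.",
                    ids[i], paste(dim(v), collapse = "x"),
                    paste(d, collapse = "x")),
            class = "adfs_geometry_error")
    }
    out[, , , i] <- v
  }
  if (!is.null(stats)) {
    out <- sweep(out, 3, stats$mean, "-")
    out <- sweep(out, 3, stats$sd, "/")
  }
  out
}
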