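#' Read a dense-text Hi-C matrix
#'
#' Reads a whitespace-delimited square matrix (the canonical, download-free
#' exchange format here). Upper-triangular inputs (zeros or NA below the
#' diagonal) are completed by symmetry. A genuinely asymmetric matrix is
#' rejected unless `symmetrize = TRUE`, in which case mismatching entries are
#' averaged; silent averaging would hide upstream errors, so strict mode is
#' the default.
#'
#' @param path File path.
#' @param locus [locus_spec()] the matrix must match.
#' @param normalized Whether the values are already normalized frequencies.
#' @param symmetrize Average asymmetric entries instead of erroring.
#' @return A [hic_matrix()].
#' @export
read_hic_matrix <- function(path, locus, normalized = FALSE,
                            symmetrize = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) abort("Hi-C matrix file is not square.")
  if (nrow(m) != locus$n_bins) {
    abort(sprintf(
      "Matrix has %d bins but locus declares %d.", nrow(m), locus$n_bins
    ))
  }
  m[is.na(m)] <- 0
  if (any(m < 0)) abort("Hi-C matrix has negative entries.")
  lower <- m[lower.tri(m)]
  upper <- t(m)[lower.tri(m)]
  if (all(lower == 0) && any(upper != 0)) {
    # upper triangle only: complete by symmetry
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  } else if (any(abs(lower - upper) > 1e-8 * max(1, max(abs(m))))) {
    if (!symmetrize) {
      abort("Input matrix is asymmetric; pass `symmetrize = TRUE` to average.")
    }
    m <- (m + t(m)) / 2
  }
  hic_matrix(m, locus, normalized = normalized)
}

#' Write a Hi-C matrix as dense text
#'
#' @param hic A [hic_matrix()] or plain matrix.
#' @param path Output path.
#' @export
write_hic_matrix <- function(hic, path) {
  m <- hic_values(hic)
  # %.17g preserves doubles exactly across a text round-trip
  readr::write_lines(
    apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
    path
  )
  invisible(path)
}

#' Read BED annotations (super-enhancer / enhancer / promoter)
#'
#' Expects BED3 plus a label column drawn from `SE`, `E`, `P`. Coordinates
#' are 0-based half-open. Intervals are clipped to the locus; intervals
#' entirely outside it are dropped (with a message), and unknown labels are
#' skipped with a warning. Malformed lines are a hard error naming the line.
#'
#' @param path BED file path.
#' @param locus [locus_spec()].
#' @return An `annotation_track`: tibble of `start`, `end`, `label` with the
#'   locus attached as an attribute.
#' @export
read_bed_annotations <- function(path, locus) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 4 || is.na(suppressWarnings(as.numeric(f[2]))) ||
      is.na(suppressWarnings(as.numeric(f[3])))) {
      abort(sprintf("Malformed BED line %d: '%s'", k, lines[k]))
    }
    rows[[k]] <- tibble::tibble(
      chrom = f[1], start = as.numeric(f[2]), end = as.numeric(f[3]),
      label = f[4]
    )
  }
  bed <- dplyr::bind_rows(rows)
  bad <- !bed$label %in% c("SE", "E", "P")
  if (any(bad)) {
    warn(sprintf(
      "Skipping %d interval(s) with unknown label(s): %s",
      sum(bad), paste(unique(bed$label[bad]), collapse = ", ")
    ))
    bed <- bed[!bad, ]
  }
  keep <- bed$chrom == locus$chrom & bed$end > locus$start &
    bed$start < locus$end
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("Dropped %d interval(s) outside the locus.", n_drop))
  }
  bed <- bed[keep, ]
  out <- tibble::tibble(
    start = pmax(bed$start, locus$start),
    end = pmin(bed$end, locus$end),
    label = bed$label
  )
  structure(out, locus = locus, class = c("annotation_track", class(out)))
}

#' Per-bin label sets from an annotation track
#'
#' A bin carries a label when it overlaps any interval with that label; bins
#' may carry several labels (overlapping intervals are all retained).
#'
#' @param annotations An `annotation_track` from [read_bed_annotations()] (or
#'   a tibble of `start`, `end`, `label` with a `locus` attribute).
#' @param locus Optional [locus_spec()] override.
#' @return Tibble `bin`, `SE`, `E`, `P` (logical flags), one row per bin.
#' @export
annotate_bins <- function(annotations, locus = NULL) {
  locus <- locus %||% attr(annotations, "locus")
  if (is.null(locus)) abort("No locus attached to the annotation track.")
  out <- tibble::tibble(
    bin = seq_len(locus$n_bins), SE = FALSE, E = FALSE, P = FALSE
  )
  rng <- bin_ranges(locus)
  for (k in seq_len(nrow(annotations))) {
    hit <- rng$start < annotations$end[k] & rng$end > annotations$start[k]
    lab <- annotations$label[k]
    out[[lab]][hit] <- TRUE
  }
  out
}

#' Read per-bin feature tracks
#'
#' Accepts either a wide TSV (`bin` column plus one numeric column per track)
#' or a bedGraph-style file per track. Wide TSV is the canonical fixture
#' format.
#'
#' @param path TSV path.
#' @param locus [locus_spec()]; bins must cover the locus.
#' @return Tibble with `bin` and one column per feature track.
#' @export
read_feature_tracks <- function(path, locus) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"bin" %in% names(tab)) abort("Feature table needs a `bin` column.")
  if (nrow(tab) != locus$n_bins) {
    abort(sprintf(
      "Feature table has %d rows but locus has %d bins.",
      nrow(tab), locus$n_bins
    ))
  }
  tab[order(tab$bin), ]
}

#' Write / read SPRITE-like cluster data
#'
#' One cluster per line: whitespace-separated 1-based bin indices of the
#' co-captured regions.
#'
#' @param clusters List of integer vectors.
#' @param path File path.
#' @name cluster_io
#' @export
write_clusters <- function(clusters, path) {
  readr::write_lines(vapply(clusters, paste, "", collapse = " "), path)
  invisible(path)
}

#' @param locus Optional [locus_spec()] used to validate indices.
#' @rdname cluster_io
#' @export
read_clusters <- function(path, locus = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  cl <- lapply(lines, function(x) as.integer(strsplit(trimws(x), "\\s+")[[1]]))
  if (!is.null(locus)) {
    rng <- range(unlist(cl))
    if (rng[1] < 1 || rng[2] > locus$n_bins) {
      abort("Cluster bin index outside the locus.")
    }
  }
  if (any(lengths(cl) < 1)) abort("Empty cluster record.")
  cl
}

#' Write a conformation ensemble to a multi-model file
#'
#' `xyz` writes one model block per conformation (`n_beads`, a comment line
#' with the model index and log-weight, then `C x y z` rows in nm). `pdb`
#' writes multi-MODEL CA traces in Angstrom; coordinates exceeding the fixed
#' PDB field width are uniformly scaled down with a warning.
#'
#' @param ensemble A `chromatin_ensemble` (or reconstructed ensemble).
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_ensemble <- function(ensemble, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  m <- n_conformations(ensemble)
  if (m == 0) abort("Refusing to write an empty ensemble.")
  n <- dim(ensemble$coords)[1]
  lw <- ensemble$log_weights
  if (format == "xyz") {
    out <- character(0)
    for (k in seq_len(m)) {
      xyz <- ensemble$coords[, , k]
      out <- c(
        out, as.character(n),
        sprintf("model %d log_weight %.17g", k, lw[k]),
        sprintf("C %.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3])
      )
    }
    readr::write_lines(out, path)
  } else {
    ang <- ensemble$coords * 10 # nm -> Angstrom
    scale <- 1
    if (max(abs(ang)) >= 10000) { # PDB 8.3 coordinate field limit
      scale <- 9999 / max(abs(ang))
      warn(sprintf(
        "Coordinates exceed the PDB field width; scaled by %.4g.", scale
      ))
      ang <- ang * scale
    }
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(m)) {
      writeLines(sprintf("MODEL %8d", k), con)
      xyz <- ang[, , k]
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3]
      ), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read an xyz multi-model ensemble written by [write_ensemble()]
#'
#' @param path File path.
#' @param params Optional [polymer_params()] to attach.
#' @return A `chromatin_ensemble` (kind `"loaded"`).
#' @export
read_ensemble <- function(path, params = NULL) {
  lines <- readr::read_lines(path)
  i <- 1
  coords <- list()
  lws <- numeric(0)
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- strsplit(lines[i + 1], "\\s+")[[1]]
    lws <- c(lws, as.numeric(hdr[4]))
    block <- lines[(i + 2):(i + 1 + n)]
    xyz <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(f) {
      as.numeric(f[2:4])
    }))
    coords[[length(coords) + 1]] <- xyz
    i <- i + 2 + n
  }
  arr <- array(0, dim = c(nrow(coords[[1]]), 3, length(coords)))
  for (k in seq_along(coords)) arr[, , k] <- coords[[k]]
  structure(
    list(
      coords = arr, log_weights = lws, params = params, kind = "loaded",
      constraint_set = NULL, confinement_radius = NA_real_, seed = NA,
      diagnostics = list()
    ),
    class = "chromatin_ensemble"
  )
}

#' Write / read contact-call tables and cell states as JSON
#'
#' @param x A tibble of contact calls, or a binary state matrix.
#' @param path File path.
#' @name json_io
#' @export
write_calls_json <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname json_io
#' @export
read_calls_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname json_io
#' @export
write_states_json <- function(x, path) {
  jsonlite::write_json(
    list(n_cells = nrow(x), n_contacts = ncol(x), states = unname(as.matrix(x))),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname json_io
#' @export
read_states_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(as.integer(obj$states), nrow = obj$n_cells, ncol = obj$n_contacts)
}
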