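# Domain types and on-disk formats: FASTA sequences, CASP RR predictions,
# per-protein feature bundles, contact maps derived from coordinates, and
# sequence-separation range masks.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Protein record
#'
#' @param id identifier string.
#' @param sequence amino-acid sequence (20-letter alphabet plus X); length
#'   must be at least 2.
#' @return object of class `protein_record` with fields `id`, `sequence`, `L`.
#' @export
protein_record <- function(id, sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0) {
    stop("protein_record '", id, "': illegal residue character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  L <- nchar(sequence)
  if (L < 2L) stop("protein_record '", id, "': sequence length must be >= 2")
  structure(list(id = id, sequence = sequence, L = L), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (L = ", x$L, ")\n", sep = "")
  invisible(x)
}

#' Contact map
#'
#' An `L x L` matrix of residue-residue contacts: binary (true contacts,
#' symmetric with zero diagonal) or probabilistic (predictions in \[0, 1\]).
#'
#' @param values numeric `L x L` matrix.
#' @param kind `"binary"` or `"probability"`.
#' @param valid optional logical `L x L` validity mask (FALSE where either
#'   residue has no coordinates).
#' @return object of class `contact_map` with fields `values`, `kind`, `valid`.
#' @export
contact_map <- function(values, kind = c("probability", "binary"), valid = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary contact_map entries must be 0/1")
    if (any(diag(values) != 0)) stop("binary contact_map must have zero diagonal")
    if (!isTRUE(all.equal(values, t(values)))) stop("binary contact_map must be symmetric")
  } else {
    if (any(values < 0 | values > 1)) stop("probability contact_map entries must lie in [0,1]")
  }
  structure(list(values = values, kind = kind, valid = valid),
            class = "contact_map")
}

map_values <- function(x) if (inherits(x, "contact_map")) x$values else x

#' Per-residue representative-atom coordinates
#'
#' One representative atom per residue (C-beta; C-alpha for glycine by the
#' usual CASP convention), in Angstrom.
#'
#' @param coords numeric `L x 3` matrix.
#' @param mask logical length-L vector, FALSE for missing residues.
#' @return object of class `residue_coords`.
#' @export
residue_coords <- function(coords, mask = rep(TRUE, nrow(coords))) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, length(mask) == nrow(coords))
  if (any(!is.finite(coords[mask, ]))) {
    stop("residue_coords: non-finite coordinates for unmasked residues")
  }
  structure(list(coords = coords, mask = mask), class = "residue_coords")
}

#' Feature set for one protein
#'
#' The paired model inputs: a sequence profile (PSSM, `L x 20`) and a
#' coevolution coupling tensor (PLM, `L x L x C`; C = 441 in the published
#' feature pipeline, configurable here).
#'
#' @param pssm numeric `L x 20` matrix.
#' @param plm numeric `L x L x C` array.
#' @param contacts optional true [contact_map()] (binary).
#' @param record optional [protein_record()].
#' @return object of class `feature_set`.
#' @export
feature_set <- function(pssm, plm, contacts = NULL, record = NULL) {
  stopifnot(is.matrix(pssm), length(dim(plm)) == 3L)
  L <- nrow(pssm)
  if (dim(plm)[1] != dim(plm)[2]) stop("feature_set: PLM first two dimensions must be equal")
  if (dim(plm)[1] != L) {
    stop("feature_set: L mismatch between PSSM (L=", L, ") and PLM (L=", dim(plm)[1], ")")
  }
  if (!all(is.finite(pssm)) || !all(is.finite(plm))) {
    stop("feature_set: all feature entries must be finite")
  }
  if (!is.null(contacts) && nrow(map_values(contacts)) != L) {
    stop("feature_set: L mismatch between features (L=", L,
         ") and contact map (L=", nrow(map_values(contacts)), ")")
  }
  if (!is.null(record) && record$L != L) {
    stop("feature_set: L mismatch between features and protein record")
  }
  structure(list(pssm = pssm, plm = plm, contacts = contacts, record = record,
                 L = L, C = dim(plm)[3]),
            class = "feature_set")
}

# ---- FASTA ------------------------------------------------------------------

#' Read protein sequences from FASTA
#'
#' Parsing goes through `Biostrings::readAAStringSet`; sequences are
#' upper-cased and validated against the 20-letter amino-acid alphabet plus
#' X. With `strict = TRUE` (default), whitespace inside a sequence line is a
#' format error; otherwise it is silently stripped.
#'
#' @param path FASTA file path.
#' @param strict reject whitespace inside sequence lines?
#' @return list of [protein_record()].
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seq_lines <- which(!startsWith(trimws(lines), ">") & nzchar(trimws(lines)))
  ws <- seq_lines[grepl("\\s", trimws(lines[seq_lines]))]
  if (length(ws) > 0) {
    if (strict) {
      stop("read_fasta: whitespace inside sequence at line ", ws[1], " of ", path)
    }
    lines[ws] <- gsub("\\s", "", lines[ws])
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(lines, path)
  }
  for (k in seq_lines) {
    chars <- strsplit(toupper(trimws(lines[k])), "")[[1]]
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad) > 0) {
      stop("read_fasta: illegal residue character(s) ",
           paste(unique(bad), collapse = ", "), " at line ", k, " of ", path)
    }
  }
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop("read_fasta: malformed FASTA: ",
                                         conditionMessage(e)))
  if (length(x) == 0) stop("read_fasta: no sequences found in ", path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  lapply(seq_along(x), function(k) protein_record(ids[k], as.character(x[[k]])))
}

#' Write protein records to FASTA
#'
#' @param records list of [protein_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) writeLines(c(paste0(">", r$id), r$sequence), con)
  invisible(path)
}

# ---- contacts from coordinates ---------------------------------------------

#' Derive a binary contact map from residue coordinates
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms is strictly less than `threshold` (8.0 Angstrom by
#' the CASP definition). Pairs involving masked (missing) residues are 0 and
#' flagged invalid in the returned validity mask.
#'
#' @param coords a [residue_coords()] or plain `L x 3` matrix.
#' @param threshold contact distance threshold in Angstrom (default 8.0).
#' @return a binary [contact_map()] whose `valid` field marks pairs where
#'   both residues are present (diagonal invalid).
#' @export
contacts_from_coords <- function(coords, threshold = 8.0) {
  stopifnot(threshold > 0)
  if (!inherits(coords, "residue_coords")) coords <- residue_coords(coords)
  L <- nrow(coords$coords)
  if (sum(coords$mask) < 2L) {
    stop("contacts_from_coords: need at least 2 unmasked residues")
  }
  xy <- coords$coords
  xy[!coords$mask, ] <- 0  # placeholder; masked pairs zeroed below
  D <- as.matrix(stats::dist(xy))
  m <- (D < threshold) * 1
  diag(m) <- 0
  valid <- outer(coords$mask, coords$mask, `&`)
  diag(valid) <- FALSE
  m[!valid] <- 0
  dimnames(m) <- NULL
  dimnames(valid) <- NULL
  contact_map(m, kind = "binary", valid = valid)
}

# ---- separation ranges ------------------------------------------------------

SEP_RANGES <- list(short = c(6L, 11L), medium = c(12L, 23L), long = c(24L, Inf))

#' Sequence-separation range mask
#'
#' Standard CASP separation classes on `|i - j|`: short 6-11, medium 12-23,
#' long >= 24 residues.
#'
#' @param L protein length (>= 2).
#' @param range `"short"`, `"medium"` or `"long"`.
#' @return symmetric logical `L x L` matrix with FALSE diagonal.
#' @export
range_mask <- function(L, range = c("long", "medium", "short")) {
  range <- match.arg(range)
  stopifnot(L >= 2L)
  b <- SEP_RANGES[[range]]
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  sep >= b[1] & sep <= b[2]
}

# ---- CASP RR format ---------------------------------------------------------

#' Write predicted contacts in CASP RR format
#'
#' Header line with the sequence, then one line per upper-triangle pair:
#' `i j 0 8 p` (1-based, i < j, probability to 6 decimals), sorted by
#' descending probability with ties broken by (i, j) ascending.
#'
#' @param pred probability [contact_map()].
#' @param record the target's [protein_record()].
#' @param path output path.
#' @param top_k maximum number of pair lines (default all).
#' @return `path`, invisibly.
#' @export
write_rr <- function(pred, record, path, top_k = Inf) {
  stopifnot(inherits(pred, "contact_map"))
  if (pred$kind != "probability") stop("write_rr: prediction must be a probability map")
  v <- pred$values
  L <- nrow(v)
  if (L != record$L) stop("write_rr: map size does not match record length")
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ord <- order(-v[ut], ut[, 1], ut[, 2])
  ord <- ord[seq_len(min(length(ord), top_k))]
  lines <- c(record$sequence,
             sprintf("%d %d 0 8 %.6f", ut[ord, 1], ut[ord, 2], v[ut[ord, , drop = FALSE]]))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("write_rr: cannot open ", path, " for writing"))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a CASP RR prediction file
#'
#' @param path RR file path.
#' @return list with `sequence` (string), `L`, and `pairs`, a tibble with
#'   columns `i`, `j`, `prob` in file order.
#' @export
read_rr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_pair <- grepl("^\\s*\\d+\\s+\\d+\\s", lines)
  seqline <- paste0(lines[!is_pair & !grepl("^(PFRMAT|TARGET|MODEL|END)", lines)],
                    collapse = "")
  fields <- strsplit(trimws(lines[is_pair]), "\\s+")
  pairs <- tibble::tibble(
    i = vapply(fields, function(f) as.integer(f[1]), integer(1)),
    j = vapply(fields, function(f) as.integer(f[2]), integer(1)),
    prob = vapply(fields, function(f) as.numeric(f[5]), numeric(1))
  )
  list(sequence = seqline, L = nchar(seqline), pairs = pairs)
}

#' Convert parsed RR pairs to a probability contact map
#'
#' @param rr result of [read_rr()].
#' @param L protein length (defaults to the header sequence length).
#' @return probability [contact_map()] (symmetric; unlisted pairs are 0).
#' @export
rr_to_map <- function(rr, L = rr$L) {
  v <- matrix(0, L, L)
  v[cbind(rr$pairs$i, rr$pairs$j)] <- rr$pairs$prob
  v[cbind(rr$pairs$j, rr$pairs$i)] <- rr$pairs$prob
  contact_map(v, "probability")
}

# ---- feature bundles --------------------------------------------------------

#' Write a per-protein feature bundle
#'
#' One file per protein holding the keyed arrays (PSSM, PLM, optional true
#' contact map) plus shape metadata, via R's native serialization; the round
#' trip is bit-exact.
#'
#' @param fs a [feature_set()].
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_feature_bundle <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  saveRDS(list(format = "contattn_bundle", version = 1L,
               L = fs$L, C = fs$C,
               pssm = fs$pssm, plm = fs$plm,
               contacts = fs$contacts, record = fs$record),
          path)
  invisible(path)
}

#' Read a per-protein feature bundle
#'
#' @param path bundle path written by [write_feature_bundle()].
#' @return a [feature_set()].
#' @export
read_feature_bundle <- function(path) {
  if (!file.exists(path)) stop("read_feature_bundle: file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "contattn_bundle")) {
    stop("read_feature_bundle: not a contattn feature bundle: ", path)
  }
  if (nrow(x$pssm) != x$L || dim(x$plm)[1] != x$L) {
    stop("read_feature_bundle: integrity error, stored L values disagree in ", path)
  }
  feature_set(x$pssm, x$plm, contacts = x$contacts, record = x$record)
}

#' Read a plain-text whitespace-separated PSSM matrix
#'
#' For externally produced profiles: L rows of 20 whitespace-separated
#' numbers.
#'
#' @param path text file path.
#' @return numeric `L x 20` matrix.
#' @export
read_pssm_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 20L) stop("read_pssm_matrix: expected 20 columns, got ", ncol(m))
  if (!all(is.finite(m))) stop("read_pssm_matrix: non-finite entries in ", path)
  dimnames(m) <- NULL
  m
}
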