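#' @importFrom utils read.delim write.table
NULL

#' Sentinel used for drug records whose raw name has no canonical mapping
#' @export
UNMAPPED <- "UNMAPPED"

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  if (nrow(df) == 0L && ncol(df) == 0L) stop("empty file: ", path, call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a clinical table
#'
#' Reads a tab-separated clinical table with one row per patient carrying the
#' cancer-type code, the survival time in days and the event indicator
#' (1 = death observed, 0 = censored). Column names differ between cohort
#' dialects (TCGA, GEO exports), so the mapping is configurable.
#'
#' Rows with missing survival time or event are dropped; the number and row
#' indices of dropped rows are attached as the \code{"drop_report"} attribute.
#'
#' @param path path to a tab-separated file with a header row.
#' @param columns named list mapping the roles \code{patient}, \code{cancer},
#'   \code{time}, \code{event} to column names in the file.
#' @return a data.frame with columns \code{patient_id}, \code{cancer_type},
#'   \code{survival_time}, \code{event}, with attribute \code{drop_report}.
#' @export
read_clinical <- function(path,
                          columns = list(patient = "patient_id",
                                         cancer = "cancer_type",
                                         time = "survival_time",
                                         event = "event")) {
  df <- read_tsv_checked(path)
  for (role in c("patient", "cancer", "time", "event")) {
    nm <- columns[[role]]
    if (is.null(nm) || !nm %in% names(df))
      stop("clinical table is missing required column \"",
           if (is.null(nm)) role else nm, "\" (role: ", role, ")", call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(df[[columns$patient]]),
                    cancer_type = as.character(df[[columns$cancer]]),
                    survival_time = suppressWarnings(as.numeric(df[[columns$time]])),
                    event = suppressWarnings(as.numeric(df[[columns$event]])),
                    stringsAsFactors = FALSE)
  drop <- which(is.na(out$survival_time) | is.na(out$event))
  if (length(drop)) out <- out[-drop, , drop = FALSE]
  if (any(out$survival_time < 0)) {
    bad <- which(out$survival_time < 0)[1L]
    stop("negative survival time at row ", bad, call. = FALSE)
  }
  if (!all(out$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  if (anyDuplicated(out$patient_id))
    stop("duplicated patient_id in clinical table: ",
         out$patient_id[duplicated(out$patient_id)][1L], call. = FALSE)
  rownames(out) <- NULL
  attr(out, "drop_report") <- list(n_dropped = length(drop), rows = drop)
  out
}

#' Normalize a raw drug name
#'
#' Lowercases, trims, collapses internal whitespace and strips trailing
#' punctuation, so that spelling variants of the same drug compare equal
#' before mapping lookup.
#'
#' @param x character vector of raw drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' Standardize drug names against a mapping table
#'
#' Treatment records in public cohorts carry free-text drug names with
#' inconsistent conventions; screening requires one canonical name per drug.
#' Each raw name is normalized (see \code{\link{normalize_drug_name}}) and
#' looked up in the mapping; names absent from the mapping become
#' \code{UNMAPPED} and are excluded from group building.
#'
#' Already-canonical names whose normalized form appears as a canonical value
#' in the mapping pass through unchanged, making the operation idempotent.
#'
#' @param records data.frame with columns \code{patient_id}, \code{raw_name}.
#' @param mapping data.frame with columns \code{raw}, \code{canonical}.
#' @return \code{records} with an added \code{standardized_name} column;
#'   attribute \code{n_unmapped} counts unmapped records.
#' @export
standardize_drugs <- function(records, mapping) {
  stopifnot(all(c("patient_id", "raw_name") %in% names(records)),
            all(c("raw", "canonical") %in% names(mapping)))
  key <- normalize_drug_name(mapping$raw)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k)
      length(unique(mapping$canonical[key == k])) > 1L, logical(1))
    if (any(conflict))
      stop("conflicting mapping for raw drug name \"",
           unique(dup)[conflict][1L], "\"", call. = FALSE)
    keep <- !duplicated(key)
    mapping <- mapping[keep, , drop = FALSE]
    key <- key[keep]
  }
  lut <- stats::setNames(as.character(mapping$canonical), key)
  norm <- normalize_drug_name(records$raw_name)
  std <- unname(lut[norm])
  # pass-through for names that are already canonical
  canon <- normalize_drug_name(mapping$canonical)
  idx <- is.na(std) & norm %in% canon
  std[idx] <- mapping$canonical[match(norm[idx], canon)]
  std[is.na(std)] <- UNMAPPED
  records$standardized_name <- std
  attr(records, "n_unmapped") <- sum(std == UNMAPPED)
  records
}

#' Read an expression matrix
#'
#' Reads a tab-separated log-scale expression table, first column feature
#' ids, remaining columns one per sample. Non-numeric cells become missing
#' values; the total number of missing cells is recorded in the
#' \code{"n_missing"} attribute.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("expression table needs a feature column and at least one sample", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[duplicated(ids)][1L], call. = FALSE)
  raw <- df[, -1L, drop = FALSE]
  vals <- vapply(raw, function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(df)))
  m <- matrix(vals, nrow = nrow(df), dimnames = list(ids, names(raw)))
  attr(m, "n_missing") <- sum(is.na(m))
  m
}

#' Write an expression matrix in the tab-separated dialect read back by
#' \code{\link{read_expression}}
#' @param m numeric matrix, features in rows.
#' @param path output path.
#' @param id_column name for the feature-id column.
#' @export
write_expression <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  write_tsv(df, path)
}

#' Read miRNA-target pair tables
#'
#' Reads one or more tab-separated tables of experimentally supported
#' miRNA-target gene pairs (the union of databases such as TarBase and
#' miRTarBase) and de-duplicates on (miRNA, gene). A missing regulation
#' column defaults to \code{unknown}; the same pair labeled both
#' \code{inhibit} and \code{activate} across sources resolves to
#' \code{unknown} and is recorded in the \code{"conflicts"} attribute.
#'
#' @param paths character vector of file paths.
#' @param columns named list mapping roles \code{mirna}, \code{gene},
#'   \code{regulation} to column names.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{regulation}, \code{source}.
#' @export
read_target_pairs <- function(paths,
                              columns = list(mirna = "mirna_id",
                                             gene = "gene_id",
                                             regulation = "regulation")) {
  pieces <- lapply(paths, function(p) {
    df <- read_tsv_checked(p)
    for (role in c("mirna", "gene"))
      if (!columns[[role]] %in% names(df))
        stop("target-pair table ", p, " is missing column \"",
             columns[[role]], "\"", call. = FALSE)
    reg <- if (columns$regulation %in% names(df))
      as.character(df[[columns$regulation]]) else rep(NA_character_, nrow(df))
    reg[is.na(reg) | !reg %in% c("inhibit", "activate")] <- "unknown"
    ok <- !is.na(df[[columns$mirna]]) & !is.na(df[[columns$gene]])
    data.frame(mirna_id = as.character(df[[columns$mirna]])[ok],
               gene_id = as.character(df[[columns$gene]])[ok],
               regulation = reg[ok],
               source = basename(p), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  key <- paste(all$mirna_id, all$gene_id, sep = "\r")
  regs <- split(all$regulation, key)[unique(key)]
  first <- all[!duplicated(key), , drop = FALSE]
  resolved <- vapply(regs, function(r) {
    r <- setdiff(unique(r), "unknown")
    if (length(r) == 1L) r else if (length(r) == 0L) "unknown" else "conflict"
  }, character(1))
  conflicts <- first[resolved == "conflict", c("mirna_id", "gene_id")]
  resolved[resolved == "conflict"] <- "unknown"
  first$regulation <- unname(resolved)
  src <- vapply(split(all$source, key)[unique(key)],
                function(s) paste(unique(s), collapse = ";"), character(1))
  first$source <- unname(src)
  rownames(first) <- NULL
  attr(first, "conflicts") <- conflicts
  first
}
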