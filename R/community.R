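#' Validate a community count matrix
#'
#' A community table is an integer matrix of sequencing read counts with
#' samples as rows and OTUs as columns; row names are sample ids and column
#' names are OTU ids. This checks the structural invariants shared by all
#' downstream analyses: unique ids, non-negative integer counts.
#'
#' @param counts A numeric matrix, samples x OTUs, with dimnames.
#' @return The validated matrix, invisibly coerced to integer storage.
#' @export
validate_community <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (anyNA(counts)) stop("`counts` contains missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count %s at sample '%s', OTU '%s' (must be a non-negative integer)",
                 format(counts[bad[1, , drop = FALSE]]),
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  counts
}

#' Read a community table from TSV/CSV
#'
#' Expects a header row of OTU ids and a first column of sample ids.
#'
#' @param path File path.
#' @param delim Field delimiter: `"tab"` (default) or `"comma"`.
#' @return An integer matrix, samples x OTUs.
#' @export
read_community <- function(path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  sep <- if (delim == "tab") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("community file must have a sample-id column and at least one OTU column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) , arr.ind = TRUE)
    stop(sprintf("non-numeric count at sample '%s', OTU '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  validate_community(m)
}

#' Write a community table to TSV/CSV
#'
#' `read_community(write_community(x, path), ...)` round-trips exactly.
#'
#' @param counts Community matrix (samples x OTUs).
#' @param path Output path.
#' @param delim `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_community <- function(counts, path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  counts <- validate_community(counts)
  sep <- if (delim == "tab") "\t" else ","
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate sample metadata
#'
#' Metadata carries one row per sample: `sample_id`, `kind` (`"root"` or
#' `"soil"`), `position_id`, coordinates `x`/`y` in metres, and `host_plant`
#' (a plant genus for root samples, `NA` for soil samples). Each position has
#' at most one soil sample and every root sample names a host plant.
#'
#' @param metadata A data frame with the columns above.
#' @return A validated tibble.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "kind", "position_id", "x", "y", "host_plant")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  md <- tibble::as_tibble(metadata)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(md$kind %in% c("root", "soil"))) stop("`kind` must be 'root' or 'soil'")
  if (!all(is.finite(md$x)) || !all(is.finite(md$y))) stop("coordinates must be finite")
  root <- md[md$kind == "root", ]
  if (any(is.na(root$host_plant) | root$host_plant == ""))
    stop("every root sample must have a host_plant")
  soil <- md[md$kind == "soil", ]
  if (anyDuplicated(soil$position_id))
    stop("more than one soil sample at position ",
         soil$position_id[duplicated(soil$position_id)][1])
  md
}

#' Read sample metadata from TSV
#'
#' @param path File path to a tab-separated file with columns `sample_id`,
#'   `kind`, `position_id`, `x`, `y`, `host_plant`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8", na.strings = c("NA", ""))
  for (col in c("sample_id", "kind", "position_id", "host_plant"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  validate_metadata(df)
}

#' Read an OTU-to-guild map from a two-column TSV
#'
#' Guilds follow the controlled vocabulary used for root-associated fungi:
#' EcMF, AMF, Endophyte, Pathogen, Mycoparasite, Nematophagous, Other_RAF,
#' Unassigned, Unidentified.
#'
#' @param path File path.
#' @return A tibble with columns `otu_id`, `guild`.
#' @export
read_guild_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("otu_id", "guild") %in% names(df)))
    stop("guild map must have columns otu_id, guild")
  validate_guild_map(tibble::as_tibble(df))
}

guild_levels <- function() {
  c("EcMF", "AMF", "Endophyte", "Pathogen", "Mycoparasite",
    "Nematophagous", "Other_RAF", "Unassigned", "Unidentified")
}

validate_guild_map <- function(guilds, otu_ids = NULL) {
  bad <- setdiff(unique(guilds$guild), guild_levels())
  if (length(bad) > 0) stop("unknown guild label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(guilds$otu_id)) stop("duplicate otu_id in guild map")
  if (!is.null(otu_ids)) {
    miss <- setdiff(otu_ids, guilds$otu_id)
    if (length(miss) > 0)
      stop("guild map does not cover OTU(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  guilds
}

#' Discard samples below a sequencing-depth threshold
#'
#' The study design discards root samples with fewer than 1,000 reads and
#' soil samples with fewer than 5,000 reads before rarefaction; samples whose
#' row sum is at least `min_reads` are kept, in their original order.
#'
#' @param counts Community matrix.
#' @param min_reads Minimum total reads per sample (>= 0).
#' @return The filtered community matrix (possibly with zero rows).
#' @export
filter_low_depth <- function(counts, min_reads) {
  counts <- validate_community(counts)
  stopifnot(min_reads >= 0)
  keep <- rowSums(counts) >= min_reads
  if (!any(keep)) warning("all samples removed by depth filter")
  counts[keep, , drop = FALSE]
}

#' Convert counts to presence/absence
#'
#' @param counts Community matrix.
#' @return A 0/1 integer matrix of the same shape.
#' @export
to_binary <- function(counts) {
  counts <- validate_community(counts)
  out <- (counts > 0) + 0L
  dimnames(out) <- dimnames(counts)
  out
}
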