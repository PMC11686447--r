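# Table and JSON readers/writers shared by all stages.  Comma-delimited with
# a header row is the canonical dialect; tab-delimited input is auto-detected.

detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (length(l1) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a glycan profile table
#'
#' Expects a delimited text file with a header row of glycan names and the
#' sample id in the first column.  Rows off from unit sum by more than 1e-3
#' are renormalized with a warning; negative fractions and duplicate sample
#' ids are errors.
#'
#' @param path file path.
#' @return samples x species numeric matrix with sample ids as row names.
#' @export
read_profile_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no rows in ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0)) stop("negative fractions in ", path, call. = FALSE)
  off <- abs(rowSums(m) - 1)
  if (any(off > 1e-3)) {
    warning(sum(off > 1e-3), " profile row(s) off unit sum by > 1e-3; ",
            "renormalized", call. = FALSE)
  }
  m / rowSums(m)
}

#' Write a glycan profile table
#'
#' @param profiles samples x species matrix (row names = sample ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  df <- data.frame(sample_id = rownames(profiles),
                   as.data.frame(profiles, check.names = FALSE),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table (genes in rows, samples in columns)
#'
#' @param path file path.
#' @return samples x genes numeric matrix (transposed into the modeling
#'   orientation); duplicate gene ids and non-numeric cells are errors.
#' @export
read_expression_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no rows in ", path, call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path, call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  t(m)
}

#' Write an expression table (genes in rows, samples in columns)
#'
#' @param block samples x genes matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(block, path) {
  m <- t(block)
  df <- data.frame(gene = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an enzyme parameter set to JSON
#' @param params an `enzyme_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  doc <- list(activity = as.data.frame(params$activity),
              enzymes = rownames(params$activity),
              lock_resolution_rate = params$lock_resolution_rate,
              residence_time = params$residence_time)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an enzyme parameter set from JSON
#' @param path file written by [write_params_json()].
#' @return an `enzyme_params`.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  act <- as.matrix(doc$activity)
  rownames(act) <- doc$enzymes
  enzyme_params(act, doc$lock_resolution_rate, doc$residence_time)
}

#' Write ABC chains as JSON-lines (one sample per line)
#'
#' Each line carries one retained posterior sample: chain index, parameter
#' vector, recorded distance and the simulation seed that produced it.
#'
#' @param chains list of `abc_chain`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chains_jsonl <- function(chains, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    for (i in seq_len(nrow(ch$samples))) {
      line <- jsonlite::toJSON(
        list(chain = ci, params = as.list(ch$samples[i, ]),
             distance = ch$distances[i], sim_seed = ch$sim_seeds[i]),
        auto_unbox = TRUE, digits = NA)
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read ABC chains written by [write_chains_jsonl()]
#' @param path JSON-lines file.
#' @return list of `abc_chain`-like objects (samples, distances, sim_seeds).
#' @export
read_chains_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  idx <- vapply(recs, `[[`, numeric(1), "chain")
  lapply(split(recs, idx), function(rs) {
    samples <- do.call(rbind, lapply(rs, function(r) unlist(r$params)))
    structure(list(samples = samples,
                   distances = vapply(rs, `[[`, numeric(1), "distance"),
                   sim_seeds = vapply(rs, `[[`, numeric(1), "sim_seed"),
                   param_names = colnames(samples)),
              class = "abc_chain")
  })
}
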