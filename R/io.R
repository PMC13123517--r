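# Tabular I/O in the dialects the pipeline consumes and emits. Every table
# written by a pipeline stage carries a header comment naming the producing
# stage and a hash of its parameters, so outputs are traceable to a run.

#' Read a SAG metadata table
#'
#' TSV with header columns sag_id, group, site, assembly_length,
#' completeness, contamination, gc, cds_count ("." decimal, UTF-8).
#'
#' @param path file path.
#' @return data.frame of SAG records.
#' @export
read_sag_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sag_id", "group", "assembly_length", "completeness",
           "contamination", "gc", "cds_count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sagnet("sagnet_format_error",
                paste("SAG table missing column(s):",
                      paste(miss, collapse = ", ")))
  df
}

#' Read a CAZyme annotation table
#'
#' TSV with columns genome_id, family; one row per hit, duplicates allowed.
#'
#' @param path file path.
#' @return data.frame with genome_id and family columns.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("genome_id", "family") %in% names(df)))
    stop_sagnet("sagnet_format_error",
                "annotation table needs genome_id and family columns")
  df
}

#' Read an abundance table
#'
#' TSV whose first column is the sample id and remaining columns are taxa.
#'
#' @param path file path.
#' @return samples x taxa numeric matrix with sample-id rownames.
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop_sagnet("sagnet_format_error",
                "abundance table must be non-negative and numeric")
  m
}

# short content hash (polynomial rolling hash, mod 2^31 - 1) for headers
param_hash <- function(params) {
  bytes <- utf8ToInt(paste(deparse(params), collapse = " "))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a pipeline output table
#'
#' TSV preceded by a comment line declaring the producing stage and a hash
#' of the stage parameters.
#'
#' @param df data.frame (or matrix) to write.
#' @param path destination path.
#' @param stage producing stage name.
#' @param params parameter list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, stage, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s params_hash=%s", stage,
                     param_hash(params)), con)
  if (is.matrix(df))
    df <- data.frame(id = rownames(df), as.data.frame(df),
                     check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as an edge list (and optionally GraphML)
#'
#' @param net igraph graph from [build_network()].
#' @param path edge-list TSV path (columns source, target, r, p).
#' @param graphml_path optional GraphML destination.
#' @param stage,params header metadata for the edge list.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml_path = NULL,
                          stage = "network", params = list()) {
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_data_frame(net, what = "edges")
    el <- data.frame(source = el$from, target = el$to, r = el$r, p = el$p)
  } else {
    el <- data.frame(source = character(), target = character(),
                     r = numeric(), p = numeric())
  }
  write_stage_tsv(el, path, stage, params)
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(path)
}
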