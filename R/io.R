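# Readers/writers for the plain-text formats the pipeline touches: counts
# TSV, GMT, STRING-links TSV, DEG TSV, alias maps, GraphML/edge-list export.
# All dialects are TAB-delimited UTF-8 with '#' comment lines ignored and a
# fixed C-locale decimal point.

.read_tsv <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

.msg <- function(...) {
  if (isTRUE(getOption("sololens.verbose", TRUE))) message("[sololens] ", ...)
}

#' Read a gene-by-sample count table
#'
#' Parses a TAB-delimited table whose header names the samples and whose
#' first column holds gene identifiers. Counts must be non-negative integers;
#' duplicated gene ids are rejected. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param condition_map named character vector mapping every sample id to
#'   `"untreated"` or `"treated"`.
#' @param time_label optional time-point label stored in the result.
#' @return A [PairedCounts-class] object.
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path, condition_map, time_label = NA_character_) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("count table needs a gene column and >= 1 sample")
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count for gene '", genes[bad[1, 1]], "', sample '",
         colnames(m)[bad[1, 2]], "': counts must be non-negative integers")
  dimnames(num) <- list(genes, colnames(m))
  missing <- setdiff(colnames(num), names(condition_map))
  if (length(missing))
    stop("no condition mapped for sample(s): ", paste(missing, collapse = ", "))
  PairedCounts(num, condition = condition_map[colnames(num)],
               time_label = time_label)
}

#' Write a PairedCounts table to TSV
#'
#' @param x a [PairedCounts-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path) {
  stopifnot(is(x, "PairedCounts"))
  m <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB gene1 TAB ...`.
#' Member lists are deduplicated; sets left empty after parsing are dropped
#' with a warning; a line with fewer than three fields is an error reported
#' with its line number.
#'
#' @param path path to the GMT file.
#' @return A [GeneSets-class] collection (empty file gives an empty one).
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(GeneSets(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated set id(s): ", paste(dup, collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- ids
  empty <- vapply(members, length, integer(1)) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty set(s): ",
            paste(ids[empty], collapse = ", "))
    members <- members[!empty]
    desc <- desc[!empty]
  }
  GeneSets(members, descriptions = desc)
}

#' Write a GeneSets collection in GMT format
#'
#' @param x a [GeneSets-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSets"))
  desc <- geneSetDescriptions(x)
  lines <- vapply(names(x), function(id) {
    paste(c(id, desc[[id]], x[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction table
#'
#' Accepts the STRING "links" dialect: a header naming two protein columns
#' (the first two columns) and score columns, delimited by TABs or
#' whitespace. Self-interactions are dropped (count reported), duplicate
#' unordered pairs are collapsed keeping the record with the maximum combined
#' score, and scores must be integers in 0-999.
#'
#' @param path path to the table.
#' @param score_column name of the combined-score column
#'   (default `"combined_score"`).
#' @return A data.frame of class `interaction_table` with columns
#'   `protein_a`, `protein_b`, `combined_score` and any further score
#'   (evidence channel) columns from the input.
#' @seealso [writeInteractions()]
#' @export
readInteractions <- function(path, score_column = "combined_score") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  df <- .read_tsv(path, sep = sep)
  if (!nrow(df)) {
    out <- data.frame(protein_a = character(), protein_b = character(),
                      combined_score = integer())
    class(out) <- c("interaction_table", "data.frame")
    return(out)
  }
  if (!score_column %in% colnames(df))
    stop("score column '", score_column, "' not found")
  a <- df[[1]]; b <- df[[2]]
  score <- suppressWarnings(as.numeric(df[[score_column]]))
  if (anyNA(score) || any(score < 0 | score > 999 | score != round(score)))
    stop("combined scores must be integers in 0-999")
  extra_cols <- setdiff(colnames(df)[-(1:2)], score_column)
  extra <- lapply(df[extra_cols], function(v) suppressWarnings(as.numeric(v)))
  loops <- a == b
  if (any(loops)) {
    .msg("dropped ", sum(loops), " self-interaction(s)")
    keep <- !loops
    a <- a[keep]; b <- b[keep]; score <- score[keep]
    extra <- lapply(extra, `[`, keep)
  }
  # canonical unordered orientation, then keep the max-score record per pair
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -score)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  out <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    combined_score = as.integer(score[keep]),
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]][keep]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Write an interaction table as TSV
#'
#' @param x an `interaction_table` data.frame (see [readInteractions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an externally computed DEG table
#'
#' Expects TAB-delimited columns `gene_id`, `log2fc`, `p_adj` (header
#' required). Adjusted p values must lie in \[0, 1\] and gene ids be unique.
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `deg_table`.
#' @export
readDegTable <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% colnames(df)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(gene_id = df$gene_id,
                    log2fc = as.numeric(df$log2fc),
                    p_adj = as.numeric(df$p_adj),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene id(s) in DEG table")
  ok <- is.na(out$p_adj) | (out$p_adj >= 0 & out$p_adj <= 1)
  if (!all(ok)) stop("p_adj values must lie in [0, 1]")
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Write a DEG table as TSV
#' @param x a `deg_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDegTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-protein alias map
#'
#' Two TAB-delimited columns `gene_id`, `protein_id`; used by
#' [buildNetwork()] to translate DEG gene ids into interactome protein ids.
#' Identifier namespaces are the caller's responsibility; when no map is
#' given the identity mapping is used.
#'
#' @param path path to the TSV file.
#' @return Named character vector (`gene_id` -> `protein_id`).
#' @export
readAliasMap <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("alias map needs columns gene_id, protein_id")
  stats::setNames(df[[2]], df[[1]])
}

#' Export a weighted network
#'
#' `writeNetworkGraphml()` writes GraphML (via igraph); `writeEdgeList()`
#' writes a weighted edge-list TSV (`node_a`, `node_b`, `weight`).
#'
#' @param net a [WeightedNetwork-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphml <- function(net, path) {
  stopifnot(is(net, "WeightedNetwork"))
  igraph::write_graph(networkGraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkGraphml
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "WeightedNetwork"))
  g <- networkGraph(net)
  el <- igraph::as_edgelist(g)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight
                            else numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
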