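# Readers and writers for the tabular and genomic formats the pipeline
# consumes. Canonical tabular dialect: tab-separated, UTF-8, '#' comment
# lines ignored, '.' decimal point.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; values are expression on a log-like scale. Duplicate gene or
#' sample identifiers and missing cells are rejected.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with genes as rows (rownames) and samples as
#'   columns (colnames).
#' @export
read_expression <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE, fill = FALSE,
               quote = ""),
    error = function(e) lnc_stop(paste0("failed to parse '", path, "': ",
                                        conditionMessage(e))))
  if (ncol(df) < 2) lnc_stop("expression TSV needs a gene-id column plus >=1 sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression(mat)
}

#' @rdname read_expression
#' @param expr Expression matrix (genes x samples).
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    lnc_validation_error("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    lnc_validation_error("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    lnc_validation_error("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr)))
    lnc_validation_error("duplicate sample ids in expression matrix")
  if (anyNA(expr))
    lnc_validation_error("expression matrix contains missing cells")
  expr
}

#' Read / write a clinical outcome table
#'
#' Columns: `sample_id`, `time` (non-negative follow-up time, one unit
#' throughout), `event` (1 = death observed, 0 = censored).
#'
#' @param path TSV path.
#' @return A data.frame with columns sample_id, time, event.
#' @export
read_clinical <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    lnc_stop(paste0("clinical TSV must have columns: ", paste(need, collapse = ", ")))
  validate_clinical(df[need])
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_clinical
#' @export
validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$sample_id))
    lnc_validation_error("duplicate sample ids in clinical table")
  if (any(!is.finite(clinical$time)) || any(clinical$time < 0))
    lnc_validation_error("clinical time must be finite and >= 0")
  if (!all(clinical$event %in% c(0, 1)))
    lnc_validation_error("clinical event must be 0 (censored) or 1 (death)")
  clinical
}

#' Construct a miRNA-target interaction set
#'
#' The container behind the hypergeometric test: `mirna_ids` is the miRNA
#' universe (its size is the `m` of the test), `targets_of` maps each gene to
#' the set of miRNAs it interacts with, and `gene_class` labels each gene as
#' `"lncRNA"` or `"TF"`.
#'
#' @param mirna_ids Character vector, the miRNA universe.
#' @param targets_of Named list of character vectors (gene -> miRNAs).
#' @param gene_class Named character vector (gene -> "lncRNA"/"TF").
#' @return An object of class `interaction_set`.
#' @export
interaction_set <- function(mirna_ids, targets_of, gene_class) {
  mirna_ids <- unique(as.character(mirna_ids))
  if (!all(names(gene_class) %in% names(targets_of)))
    lnc_validation_error("every classed gene needs a target set (possibly empty)")
  if (!all(names(targets_of) %in% names(gene_class)))
    lnc_validation_error("every gene with targets needs a class label")
  if (!all(gene_class %in% c("lncRNA", "TF")))
    lnc_validation_error("gene_class values must be 'lncRNA' or 'TF'")
  all_t <- unique(unlist(targets_of, use.names = FALSE))
  if (length(all_t) && !all(all_t %in% mirna_ids))
    lnc_validation_error("target set references miRNAs outside the universe")
  structure(list(mirna_ids = mirna_ids,
                 targets_of = lapply(targets_of, unique),
                 gene_class = gene_class),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set:", length(x$mirna_ids), "miRNAs,",
      sum(x$gene_class == "lncRNA"), "lncRNAs,",
      sum(x$gene_class == "TF"), "TFs\n")
  invisible(x)
}

#' Read / write miRNA-target interaction edge lists
#'
#' TSV columns: `mirna_id`, `target_id`, `target_class` ("lncRNA" or "TF").
#' The writer records the full miRNA universe in a `# mirnas:` comment so
#' that miRNAs without recorded targets survive a round trip (the universe
#' size is the `m` of the hypergeometric test).
#'
#' @param path TSV path.
#' @return For the reader, an [interaction_set()].
#' @export
read_interactions <- function(path) {
  first <- readLines(path, n = 5L)
  uni <- grep("^# mirnas:", first, value = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(df)))
    lnc_stop(paste0("interaction TSV must have columns: ",
                    paste(need, collapse = ", ")))
  mirnas <- if (length(uni)) {
    strsplit(sub("^# mirnas:\\s*", "", uni[1]), " ", fixed = TRUE)[[1]]
  } else unique(df$mirna_id)
  targets_of <- split(df$mirna_id, df$target_id)
  cls <- tapply(df$target_class, df$target_id, function(v) unique(v)[1])
  interaction_set(mirnas, targets_of, setNames(as.character(cls), names(cls)))
}

#' @rdname read_interactions
#' @param interactions An `interaction_set`.
#' @export
write_interactions <- function(interactions, path) {
  stopifnot(inherits(interactions, "interaction_set"))
  genes <- names(interactions$targets_of)
  rows <- do.call(rbind, lapply(genes, function(g) {
    t <- interactions$targets_of[[g]]
    if (!length(t)) return(NULL)
    data.frame(mirna_id = t, target_id = g,
               target_class = unname(interactions$gene_class[[g]]),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mirnas: ",
                    paste(interactions$mirna_ids, collapse = " ")), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' TSV with two columns naming the interacting TFs (header `a`, `b` or any
#' two-column header).
#'
#' @param path TSV path.
#' @return data.frame with columns `a`, `b`.
#' @export
read_ppi <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) lnc_stop("PPI TSV needs two columns")
  setNames(df[, 1:2], c("a", "b"))
}

#' Read / write an immune-infiltration score matrix
#'
#' TSV with a `sample_id` first column and one column of estimation scores
#' per immune cell type.
#'
#' @param path TSV path.
#' @return Numeric matrix, samples x cell types.
#' @export
read_infiltration <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) lnc_validation_error("infiltration matrix contains missing cells")
  if (anyDuplicated(rownames(m)))
    lnc_validation_error("duplicate sample ids in infiltration matrix")
  m
}

#' @rdname read_infiltration
#' @param infil Samples x cell-types numeric matrix.
#' @export
write_infiltration <- function(infil, path) {
  df <- data.frame(sample_id = rownames(infil), infil, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Intervals are kept 0-based half-open, as in the BED convention.
#'
#' @param path BED(6) path.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               paste0("region_", seq_along(gr)),
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param bed data.frame with chrom/start/end (0-based half-open) and
#'   optionally name, score, strand.
#' @export
write_bed <- function(bed, path) {
  strand <- if ("strand" %in% names(bed)) sub("^\\.$", "*", bed$strand) else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = strand)
  gr$name <- if ("name" %in% names(bed)) bed$name else
    paste0("region_", seq_len(nrow(bed)))
  gr$score <- if ("score" %in% names(bed)) bed$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is what the motif scanner consumes.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Export / import a gene network
#'
#' `edge_tsv` writes one row per edge with columns `source`, `target`,
#' `edge_type` plus the endpoint node types; `graphml` delegates to igraph
#' and carries `node_type` / `edge_type` attributes. Either format re-imports
#' to a network with identical node and edge sets.
#'
#' @param network An igraph gene network (vertex attribute `node_type`, edge
#'   attribute `edge_type`).
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  validate_gene_network(network)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    nt <- setNames(igraph::V(network)$node_type, igraph::V(network)$name)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     edge_type = if (igraph::ecount(network))
                       igraph::E(network)$edge_type else character(0),
                     source_type = unname(nt[el[, 1]]),
                     target_type = unname(nt[el[, 2]]),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
    return(validate_gene_network(g))
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  nodes <- unique(data.frame(
    name = c(df$source, df$target),
    node_type = c(df$source_type, df$target_type),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    df[, c("source", "target", "edge_type")], directed = FALSE,
    vertices = nodes)
  validate_gene_network(g)
}
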