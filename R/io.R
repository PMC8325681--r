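#' Build a GenomeAnnotation from a gene table
#'
#' Assigns 0-based gene-order ranks per chromosome: genes are sorted by start
#' coordinate, ties broken by \code{gene_id} (lexicographic). Coordinates are
#' 1-based inclusive.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end and
#'   optionally strand ("+"/"-", default "+").
#' @param species species tag stored with the annotation.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
genomeAnnotation <- function(genes, species) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (any(genes$end < genes$start))
    stop("format error: gene with end < start")
  if (!all(genes$strand %in% c("+", "-")))
    stop("format error: unknown strand symbol")
  if (anyDuplicated(genes$gene_id))
    stop("format error: duplicated gene_id")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- as.integer(
    stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)) - 1L
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$rank <- genes$rank
  methods::new("GenomeAnnotation", species = species, genes = gr)
}

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased; duplicate identifiers are a format error, as are
#' empty files. Identifiers are the first whitespace-delimited token of the
#' header line.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("format error: empty FASTA file")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("format error: duplicate FASTA ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  out
}

#' Read gene positions into a GenomeAnnotation
#'
#' Two dialects: a GFF3 subset (seqid, type, start, end, strand, ID
#' attribute; only features of \code{feature} type are used) and a headerless
#' 5-column TSV (gene_id, chrom, start, end, strand). Ranks are assigned as
#' in [genomeAnnotation()].
#'
#' @param path input file.
#' @param species species tag.
#' @param dialect "gff3" or "tsv".
#' @param feature GFF3 feature type used to define gene order ("gene" by
#'   default; set "mRNA" for transcript-level annotations).
#' @param header whether the TSV has a header line.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readGenePositions <- function(path, species,
                              dialect = c("gff3", "tsv"),
                              feature = "gene", header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("format error: ", conditionMessage(e)))
    gr <- gr[as.character(gr$type) == feature]
    if (length(gr) == 0L)
      stop("format error: no '", feature, "' features in ", path)
    ids <- gr$ID
    if (is.null(ids) || any(is.na(ids)))
      stop("format error: missing ID attribute on ", feature, " features")
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  } else {
    genes <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
    if (ncol(genes) < 4L) stop("format error: TSV needs >= 4 columns")
    names(genes)[1:4] <- c("gene_id", "chrom", "start", "end")
    if (ncol(genes) >= 5L) names(genes)[5] <- "strand" else genes$strand <- "+"
    genes$chrom <- as.character(genes$chrom)
    genes$gene_id <- as.character(genes$gene_id)
  }
  genomeAnnotation(genes, species)
}

#' Write gene positions as TSV
#'
#' Emits the 5-column TSV dialect read by [readGenePositions()]; a
#' write-then-read round trip reproduces the annotation exactly.
#'
#' @param annot a \linkS4class{GenomeAnnotation}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenePositions <- function(annot, path) {
  tab <- geneTable(annot)[, c("gene_id", "chrom", "start", "end", "strand")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read Newick gene trees
#'
#' One or more trees per file (one per line or separated by semicolons).
#' Tip labels are preserved verbatim; multifurcations are allowed.
#'
#' @param path Newick file.
#' @return a list of \code{phylo} objects.
#' @export
readGeneTrees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(trees)) stop("parse error: no tree could be read from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  unclass(trees)
}

#' Read a homolog pair list
#'
#' TSV with 2 or 3 columns (id_a, id_b[, score]). Pairs are order-normalized
#' (id_a < id_b lexicographically) and deduplicated; self-pairs are dropped
#' with a warning.
#'
#' @param path TSV file.
#' @param header whether a header line is present.
#' @return data.frame with columns id_a, id_b and, when present, score.
#' @export
readPairs <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("format error: pair list needs >= 2 columns")
  names(tab)[1:2] <- c("id_a", "id_b")
  if (ncol(tab) >= 3L) names(tab)[3] <- "score"
  tab$id_a <- as.character(tab$id_a)
  tab$id_b <- as.character(tab$id_b)
  normalizePairs(tab)
}

# Order-normalize, drop self-pairs (warning) and deduplicate a pair table.
normalizePairs <- function(tab) {
  self <- tab$id_a == tab$id_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    tab <- tab[!self, , drop = FALSE]
  }
  if (nrow(tab)) {
    swap <- tab$id_a > tab$id_b
    tmp <- tab$id_a[swap]
    tab$id_a[swap] <- tab$id_b[swap]
    tab$id_b[swap] <- tmp
    tab <- tab[!duplicated(tab[, c("id_a", "id_b")]), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a pair list as TSV
#'
#' @param pairs data.frame with id_a, id_b (and optional further columns).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
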