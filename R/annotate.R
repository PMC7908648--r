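# Gene, disease-term, candidate-gene and pedigree annotation, plus the
# rare-gene-affecting filter.

#' Load gene models from GFF3 or BED
#'
#' Reads gene records (GFF3 `type == "gene"` rows, or every BED record)
#' into the internal gene table. Pseudogenes should be pre-filtered
#' upstream; rows whose `biotype` attribute contains "pseudogene" are
#' dropped when present.
#'
#' @param path GFF3 or BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  bt <- mc$biotype %||% mc$gene_biotype
  if (!is.null(bt)) gr <- gr[!grepl("pseudogene", as.character(bt))]
  mc <- S4Vectors::mcols(gr)
  gene <- mc$Name %||% mc$name %||% mc$gene_name %||% mc$ID %||%
    as.character(seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene = as.character(gene), stringsAsFactors = FALSE)
}

#' Genes overlapped by a variant
#'
#' All genes whose body overlaps the variant interval extended by
#' `padding` bases on each side; disease terms are joined per gene when a
#' mapping is supplied.
#'
#' @param chrom,start,end Variant interval.
#' @param genes Gene table (`chrom`, `start`, `end`, `gene`).
#' @param padding Interval padding in bases (default 0).
#' @param disease_terms Optional data frame (`gene`, `term`) mapping gene
#'   symbols to disease/phenotype identifiers.
#' @return Data frame `gene`, `terms` (comma-joined, "" when none).
#' @export
annotate_genes <- function(chrom, start, end, genes, padding = 0,
                           disease_terms = NULL) {
  hit <- genes$chrom == chrom &
    genes$end >= (start - padding) & genes$start <= (end + padding)
  g <- unique(genes$gene[hit])
  terms <- vapply(g, function(gn) {
    if (is.null(disease_terms)) return("")
    paste(disease_terms$term[disease_terms$gene == gn], collapse = ",")
  }, character(1))
  data.frame(gene = g, terms = unname(terms), stringsAsFactors = FALSE)
}

#' Read a PED pedigree file
#'
#' Six whitespace-separated columns: family, individual, father, mother,
#' sex, phenotype (1 unaffected, 2 affected, other/0 unknown).
#'
#' @param path PED file path.
#' @return Data frame `family`, `sample_id`, `father`, `mother`, `sex`,
#'   `status` in `{affected, unaffected, unknown}`.
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(p) < 6) stopf("PED file needs 6 columns, got %d", ncol(p))
  data.frame(family = as.character(p[[1]]), sample_id = as.character(p[[2]]),
             father = as.character(p[[3]]), mother = as.character(p[[4]]),
             sex = p[[5]],
             status = c("unknown", "unaffected", "affected")[
               ifelse(p[[6]] %in% c(1, 2), p[[6]] + 1, 1)],
             stringsAsFactors = FALSE)
}

#' Affected / unaffected carrier counts for a variant
#'
#' IA counts carriers with affected status, IUA carriers with unaffected
#' status; carriers of unknown status (including samples absent from the
#' pedigree, which trigger a warning) contribute to neither.
#'
#' @param carriers Character vector of carrier sample ids.
#' @param ped Pedigree data frame from [read_ped()].
#' @return Named integer vector `c(ia = , iua = )`.
#' @export
pedigree_counts <- function(carriers, ped) {
  carriers <- unique(carriers)
  missing <- setdiff(carriers, ped$sample_id)
  if (length(missing)) {
    warnf("sample(s) not in pedigree, treated as unknown: %s",
          paste(missing, collapse = ", "))
  }
  st <- ped$status[match(carriers, ped$sample_id)]
  c(ia = sum(st == "affected", na.rm = TRUE),
    iua = sum(st == "unaffected", na.rm = TRUE))
}

#' Restrict to rare, gene-affecting variants
#'
#' Keeps variants that are rare, overlap at least one gene and carry a
#' HIGH or PASS tranche. Idempotent; the output is a subset of the input.
#'
#' @param variants Data frame with logical `rare`, character `genes`
#'   (comma-joined, "" when none) and `tranche` columns.
#' @return The filtered data frame.
#' @export
filter_rare_gene_affecting <- function(variants) {
  need_cols(variants, c("rare", "genes", "tranche"), "variant table")
  keep <- variants$rare & !is.na(variants$genes) & variants$genes != "" &
    variants$tranche %in% c("HIGH", "PASS")
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate-gene hits among a variant's genes
#'
#' @param genes Character vector (or comma-joined string) of overlapped
#'   gene symbols.
#' @param candidate_genes Character vector of candidate gene symbols.
#' @return Comma-joined string of hits ("" when none).
#' @export
candidate_gene_hits <- function(genes, candidate_genes) {
  if (length(genes) == 1 && grepl(",", genes)) {
    genes <- strsplit(genes, ",")[[1]]
  }
  paste(intersect(genes, candidate_genes), collapse = ",")
}
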