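# Fixture serialization: plain-text formats only (BED6, FASTA, TSV, JSON).

#' Write a simulated cohort to disk as plain-text fixture files
#'
#' Emits `genes.bed` (BED6; name = gene id), `genes_biotype.tsv` (companion
#' biotype column), `promoters.fa` (record id = gene id), `beta.tsv`,
#' `sites.tsv`, `expr_mrna.tsv`, `expr_lncrna.tsv`, `samples.tsv` and
#' `truth.json`. All coordinates are 0-based half-open. Matrix TSVs carry the
#' feature/site id in the first column and one column per sample.
#'
#' @param sim A `methex_sim` from [simulate_cohort()].
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "methex_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  bed <- tibble::tibble(
    chrom = sim$genes$chrom, start = sim$genes$start, end = sim$genes$end,
    name = sim$genes$gene_id, score = 0L, strand = sim$genes$strand
  )
  readr::write_tsv(bed, p("genes.bed"), col_names = FALSE)
  readr::write_tsv(sim$genes[c("gene_id", "biotype")], p("genes_biotype.tsv"))

  seqs <- Biostrings::DNAStringSet(sim$promoters$sequence)
  names(seqs) <- sim$promoters$gene_id
  Biostrings::writeXStringSet(seqs, p("promoters.fa"))

  readr::write_tsv(sim$sites, p("sites.tsv"))
  readr::write_tsv(sim$beta, p("beta.tsv"))
  readr::write_tsv(sim$expr_mrna, p("expr_mrna.tsv"))
  readr::write_tsv(sim$expr_lncrna, p("expr_lncrna.tsv"))
  readr::write_tsv(sim$samples, p("samples.tsv"))

  truth <- list(
    planted_up_hypo = sim$truth$planted_up_hypo,
    planted_down_hyper = sim$truth$planted_down_hyper,
    planted_edges = sim$truth$planted_edges,
    promoter_class_by_gene = dplyr::mutate(
      sim$truth$promoter_class_by_gene, cls = as.character(.data$cls))
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read gene models from BED6 (+ biotype companion)
#'
#' The TSS is recovered strand-aware from the 0-based half-open interval:
#' `start` on the plus strand, `end - 1` on the minus strand.
#'
#' @param bed_file BED6 path (columns chrom, start, end, name, score, strand;
#'   no header).
#' @param biotype_file Optional TSV with columns `gene_id`, `biotype`.
#' @return A tibble of gene models (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, and `biotype` when supplied).
#' @export
read_genes_bed <- function(bed_file, biotype_file = NULL) {
  bed <- readr::read_tsv(
    bed_file,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  genes <- tibble::tibble(
    gene_id = bed$name, chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand,
    tss = as.integer(ifelse(bed$strand == "+", bed$start, bed$end - 1L))
  )
  if (!is.null(biotype_file)) {
    bt <- readr::read_tsv(biotype_file, col_types = "cc")
    genes <- dplyr::left_join(genes, bt, by = "gene_id")
  }
  genes
}

#' Read a feature-by-sample matrix TSV
#'
#' @param file TSV with a header row of sample ids and the feature/site id in
#'   the first column.
#' @return A matrix tibble (id column + one numeric column per sample).
#' @export
read_matrix_tsv <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  x[[1]] <- as.character(x[[1]])
  x[-1] <- lapply(x[-1], as.numeric)
  tibble::as_tibble(x)
}

#' Read promoter sequences from FASTA
#'
#' @param fasta_file FASTA path; record ids are gene ids.
#' @return A tibble with `gene_id` and `sequence`.
#' @export
read_promoters_fa <- function(fasta_file) {
  ss <- Biostrings::readDNAStringSet(fasta_file)
  tibble::tibble(gene_id = names(ss), sequence = as.character(ss))
}

#' Read a cohort fixture directory back into memory
#'
#' Inverse of [write_fixture()]. Promoter intervals are re-derived from the
#' gene models with the supplied geometry and the FASTA sequences attached.
#'
#' @param dir Fixture directory.
#' @param upstream,downstream Promoter geometry used when the fixture was
#'   generated (defaults 1500/500).
#' @return A list with `genes`, `promoters` (with `sequence`), `sites`,
#'   `beta`, `expr_mrna`, `expr_lncrna`, `samples`, `truth`.
#' @export
read_fixture <- function(dir, upstream = 1500L, downstream = 500L) {
  p <- function(f) file.path(dir, f)
  genes <- read_genes_bed(p("genes.bed"), p("genes_biotype.tsv"))
  promoters <- derive_promoters(genes, upstream = upstream,
                                downstream = downstream)
  fa <- read_promoters_fa(p("promoters.fa"))
  promoters <- dplyr::left_join(promoters, fa, by = "gene_id")
  tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- list(
    planted_up_hypo = as.character(tj$planted_up_hypo),
    planted_down_hyper = as.character(tj$planted_down_hyper),
    planted_edges = tibble::as_tibble(tj$planted_edges),
    promoter_class_by_gene = tibble::as_tibble(tj$promoter_class_by_gene) |>
      dplyr::mutate(cls = factor(.data$cls, levels = c("HCP", "ICP", "LCP")))
  )
  if (nrow(truth$planted_edges) == 0) {
    truth$planted_edges <- tibble::tibble(lncrna_id = character(),
                                          mrna_id = character(),
                                          direction = character())
  }
  list(
    genes = genes,
    promoters = promoters,
    sites = readr::read_tsv(p("sites.tsv"), col_types = "cci"),
    beta = read_matrix_tsv(p("beta.tsv")),
    expr_mrna = read_matrix_tsv(p("expr_mrna.tsv")),
    expr_lncrna = read_matrix_tsv(p("expr_lncrna.tsv")),
    samples = readr::read_tsv(p("samples.tsv"), col_types = "ccc"),
    truth = truth
  )
}
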