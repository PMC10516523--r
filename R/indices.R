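# Transcription-cycle metrics per gene. Pausing index (PI) is the
# promoter-proximal RPKM over the gene-body RPKM; elongation index (EI) is
# the arithmetic mean of the two; termination index (TI) is the
# termination-region RPKM over the gene-body RPKM. Regions: promoter
# proximal = TSS +/- 500 bp, gene body = TSS + 500 to TES, termination =
# TES to TES + 3 kb, all strand-aware.

#' Strand-aware index regions for each gene
#'
#' For a plus-strand gene `[s, e)`: promoter `[s-500, s+500)`, body
#' `[s+500, e)`, termination `[e, e+3000)`; minus-strand genes mirror.
#' Regions are clipped at chromosome bounds; a region clipped to width 0
#' is returned as `NA`.
#'
#' @param genes Gene tibble (`chrom`, `start`, `end`, `name`, `strand`).
#' @param chrom_sizes Chromosome sizes tibble.
#' @param promoter_flank Promoter half-width in bp (default 500).
#' @param term_flank Termination-region length in bp (default 3000).
#' @return Tibble with one row per gene: `name`, `chrom`, `strand`, and
#'   `promoter_start/end`, `body_start/end`, `term_start/end`.
#' @export
gene_regions <- function(genes, chrom_sizes, promoter_flank = 500, term_flank = 3000) {
  genes <- validate_intervals(genes, chrom_sizes = chrom_sizes, what = "genes")
  if (!all(genes$strand %in% c("+", "-"))) abort("gene_regions: genes need strand + or -")
  sizes <- chrom_size_lookup(chrom_sizes)
  clen <- unname(sizes[genes$chrom])
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  tes <- ifelse(plus, genes$end, genes$start)
  clip <- function(start, end) {
    s <- pmax(start, 0); e <- pmin(end, clen)
    bad <- e <= s
    s[bad] <- NA_real_; e[bad] <- NA_real_
    list(start = s, end = e)
  }
  prom <- clip(tss - promoter_flank, tss + promoter_flank)
  body <- clip(ifelse(plus, genes$start + promoter_flank, genes$start),
               ifelse(plus, genes$end, genes$end - promoter_flank))
  term <- clip(ifelse(plus, tes, tes - term_flank),
               ifelse(plus, tes + term_flank, tes))
  tibble(
    name = genes$name, chrom = genes$chrom, strand = genes$strand,
    gene_start = genes$start, gene_end = genes$end,
    promoter_start = prom$start, promoter_end = prom$end,
    body_start = body$start, body_end = body$end,
    term_start = term$start, term_end = term$end
  )
}

#' Pausing, elongation, and termination indices per gene
#'
#' Computes promoter, body, and termination RPKM densities independently
#' for each gene and forms `pi = d_promoter / d_body`,
#' `ei = (d_promoter + d_body) / 2`, `ti = d_termination / d_body`. Genes
#' narrower than `min_gene_width` or with any degenerate region yield
#' all-null indices with a reason code; `pi`/`ti` are null when the body
#' density is zero (EI remains defined).
#'
#' @param tags Tag tibble.
#' @param genes Gene tibble.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param library_size Library size for RPKM (default `nrow(tags)`).
#' @param min_gene_width Genes narrower than this are excluded (default
#'   1000 bp; the promoter window would swallow the body).
#' @param promoter_flank,term_flank Region geometry (see [gene_regions()]).
#' @return Tibble: `name`, `d_promoter`, `d_body`, `d_termination`, `pi`,
#'   `ei`, `ti`, `reason` (`"ok"`, `"short_gene"`, `"degenerate_region"`,
#'   or `"zero_body"`).
#' @export
compute_indices <- function(tags, genes, chrom_sizes, library_size = nrow(tags),
                            min_gene_width = 1000, promoter_flank = 500, term_flank = 3000) {
  if (library_size <= 0) abort("compute_indices: library size must be positive")
  regions <- gene_regions(genes, chrom_sizes, promoter_flank, term_flank)
  out <- tibble(
    name = regions$name,
    d_promoter = NA_real_, d_body = NA_real_, d_termination = NA_real_,
    pi = NA_real_, ei = NA_real_, ti = NA_real_, reason = "ok"
  )
  short <- (regions$gene_end - regions$gene_start) < min_gene_width
  degen <- is.na(regions$promoter_start) | is.na(regions$body_start) | is.na(regions$term_start)
  out$reason[degen] <- "degenerate_region"
  out$reason[short] <- "short_gene"
  usable <- !short & !degen
  if (any(usable)) {
    dens <- function(start, end) {
      regs <- tibble(chrom = regions$chrom[usable], start = start[usable], end = end[usable])
      region_density(tags, regs, library_size)$density
    }
    dp <- dens(regions$promoter_start, regions$promoter_end)
    db <- dens(regions$body_start, regions$body_end)
    dt <- dens(regions$term_start, regions$term_end)
    out$d_promoter[usable] <- dp
    out$d_body[usable] <- db
    out$d_termination[usable] <- dt
    out$ei[usable] <- (dp + db) / 2
    pos <- db > 0
    out$pi[usable][pos] <- dp[pos] / db[pos]
    out$ti[usable][pos] <- dt[pos] / db[pos]
    out$reason[usable][!pos] <- "zero_body"
  }
  out
}

#' Split genes into high/medium/low tertiles of an index
#'
#' Nulls are excluded; the remaining genes are ordered by value (ties
#' broken by stable gene-name order) and split into three contiguous
#' groups whose sizes differ by at most one. When all values are equal the
#' genes form one `medium` group, with a warning.
#'
#' @param x Tibble with columns `name` and `value` (e.g. a PI column
#'   renamed), or a named numeric vector.
#' @return Tibble `name`, `value`, `group` (factor low/medium/high).
#' @export
tertile_groups <- function(x) {
  if (is.numeric(x)) x <- tibble(name = names(x), value = unname(x))
  x <- as_tibble(x)[, c("name", "value")]
  x <- x[!is.na(x$value), ]
  if (nrow(x) < 3) abort("tertile_groups: need at least 3 non-null values")
  if (length(unique(x$value)) == 1) {
    warn("tertile_groups: all values equal; assigning every gene to 'medium'")
    x$group <- factor("medium", levels = c("low", "medium", "high"))
    return(x)
  }
  ord <- order(x$value, x$name)
  n <- nrow(x)
  cuts <- round(seq(0, n, length.out = 4))
  grp <- rep(c("low", "medium", "high"), times = diff(cuts))
  x$group <- factor(NA, levels = c("low", "medium", "high"))
  x$group[ord] <- grp
  x
}
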