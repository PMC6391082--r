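#' Validate and normalize a mature miRNA sequence
#'
#' Mature miRNAs are 18--26 nt RNA strings; the seed is nucleotides 2--8
#' (7 nt), whose complementarity to a 3' UTR defines the canonical site
#' classes. DNA input (T) is accepted and transcribed to RNA.
#'
#' @param sequence miRNA sequence, 5' to 3'.
#' @return List with `sequence` (uppercase RNA) and `seed` (positions
#'   2--8).
#' @export
mature_mirna <- function(sequence) {
  seq <- toupper(gsub("T", "U", toupper(sequence)))
  if (grepl("[^ACGU]", seq)) stop("miRNA sequence contains non-ACGU characters")
  if (nchar(seq) < 18L || nchar(seq) > 26L)
    stop("Mature miRNA length must be 18-26 nt, got ", nchar(seq))
  list(sequence = seq, seed = substr(seq, 2L, 8L))
}

# Reverse complement in RNA space (input/output are plain uppercase
# RNA character strings).
rna_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
}

rna_comp_base <- function(base) {
  c(A = "U", C = "G", G = "C", U = "A")[[base]]
}

#' Scan a 3' UTR for canonical miRNA seed-match sites
#'
#' Finds every occurrence of the reverse complement of the miRNA seed
#' core (positions 2--7) in the UTR and classifies each by the
#' additional determinants: a match to miRNA position 8 on the 5' side
#' of the core (m8) and an adenosine opposite miRNA position 1 on the
#' 3' side (A1). Classes, strongest first: `8mer` (m8 + A1), `7mer-m8`
#' (m8), `7mer-A1` (A1), `6mer` (core only). Each core occurrence is
#' reported once at its highest class; `start`/`end` span the matched
#' bases (1-based, inclusive, including the m8 base when matched).
#'
#' @param utr UTR sequence (character, DNA or RNA, sense orientation),
#'   or a named length-1 vector whose name is the gene.
#' @param mirna miRNA sequence or a list from [mature_mirna()].
#' @param gene Gene identifier (defaults to the name of `utr`).
#' @return Data frame: `gene`, `start`, `end`, `match_class`,
#'   `ago_supported` (initialized `NA`). Zero rows if no site.
#' @export
scan_seed_sites <- function(utr, mirna, gene = NULL) {
  if (is.null(gene)) gene <- if (!is.null(names(utr))) names(utr)[1L] else NA_character_
  if (is.character(mirna)) mirna <- mature_mirna(mirna)
  useq <- toupper(gsub("T", "U", toupper(as.character(utr))))
  if (grepl("[^ACGU]", useq)) stop("UTR sequence contains non-ACGU/T characters")
  empty <- data.frame(gene = character(), start = integer(), end = integer(),
                      match_class = character(), ago_supported = logical(),
                      stringsAsFactors = FALSE)
  core <- rna_revcomp(substr(mirna$sequence, 2L, 7L))  # 6 nt in the UTR
  m8_base <- rna_comp_base(substr(mirna$sequence, 8L, 8L))
  n <- nchar(useq)
  if (n < 6L) return(empty)
  # all core occurrences (overlapping allowed)
  starts <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(core, substr(useq, from, n), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
    if (from > n - 5L) break
  }
  if (length(starts) == 0L) return(empty)
  rows <- lapply(starts, function(q) {
    m8 <- q > 1L && substr(useq, q - 1L, q - 1L) == m8_base
    a1 <- q + 6L <= n && substr(useq, q + 6L, q + 6L) == "A"
    if (m8) {
      cls <- if (a1) "8mer" else "7mer-m8"
      s <- q - 1L; e <- q + 5L
    } else {
      cls <- if (a1) "7mer-A1" else "6mer"
      s <- q; e <- q + 5L
    }
    data.frame(gene = gene, start = s, end = e, match_class = cls,
               ago_supported = NA, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag seed sites supported by AGO2 CLIP binding intervals
#'
#' A site is AGO-supported iff its matched span lies entirely within
#' some AGO2 interval on the same transcript (full containment, not
#' mere overlap). Intervals are 1-based inclusive transcript
#' coordinates, as produced by CLIP peak tables.
#'
#' @param sites Data frame from [scan_seed_sites()] (possibly several
#'   genes).
#' @param ago_intervals Data frame with `gene`, `start`, `end`. An
#'   empty table leaves every site unsupported.
#' @return `sites` with `ago_supported` filled in.
#' @export
mark_ago_support <- function(sites, ago_intervals) {
  if (nrow(sites) == 0L) { sites$ago_supported <- logical(0); return(sites) }
  sites$ago_supported <- FALSE
  if (is.null(ago_intervals) || nrow(ago_intervals) == 0L) return(sites)
  for (i in seq_len(nrow(sites))) {
    iv <- ago_intervals[ago_intervals$gene == sites$gene[i], , drop = FALSE]
    if (nrow(iv) == 0L) next
    sites$ago_supported[i] <-
      any(iv$start <= sites$start[i] & sites$end[i] <= iv$end)
  }
  sites
}

#' Filter genes by differential expression
#'
#' Selects genes changed more than `fold_threshold`-fold in the stated
#' direction at `p < alpha` within one named comparison. Both
#' inequalities are strict, matching the ">2-fold, P < 0.05" convention.
#'
#' @param stats Data frame of per-gene statistics: `gene`, `comparison`,
#'   `log2fc` (positive = higher in the first-named condition),
#'   `p_value`.
#' @param comparison Comparison label to restrict to; must be present
#'   in `stats`.
#' @param direction `"up"` or `"down"`.
#' @param fold_threshold Linear fold-change threshold (>= 1; default 2).
#'   `1` disables the fold gate (any nonzero change in the direction).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust If `TRUE`, Benjamini-Hochberg adjusted p-values are
#'   used instead of raw ones (off by default; the screen as published
#'   uses raw p-values).
#' @return Character vector of gene identifiers.
#' @export
expression_filter <- function(stats, comparison, direction = c("up", "down"),
                              fold_threshold = 2, alpha = 0.05,
                              adjust = FALSE) {
  direction <- match.arg(direction)
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nrow(stats) == 0L) return(character())
  if (!comparison %in% stats$comparison)
    stop("Unknown comparison label: ", comparison)
  st <- stats[stats$comparison == comparison, , drop = FALSE]
  p <- if (adjust) stats::p.adjust(st$p_value, method = "BH") else st$p_value
  lfc_cut <- log2(fold_threshold)
  keep <- p < alpha &
    (if (direction == "up") st$log2fc > lfc_cut else st$log2fc < -lfc_cut)
  st$gene[keep]
}

#' Run the three-criteria miRNA target screen
#'
#' Intersects three evidence layers to nominate direct targets:
#' (1) at least one AGO-supported seed-match site in the gene's 3' UTR;
#' (2) upregulated (> `fold_threshold`-fold, p < `alpha`) in
#' miRNA-knockout vs wild-type Tregs (`KO_vs_WT_Treg`); (3)
#' downregulated in wild-type Tregs vs effector T cells
#' (`Treg_vs_Teff`). Genes present in only one comparison are excluded
#' with a warning, never an error.
#'
#' @param utrs Named character vector of UTR sequences (names = genes),
#'   e.g. from [read_fasta()]. Ignored when `site_table` is given.
#' @param mirna miRNA sequence or [mature_mirna()] list.
#' @param ago_intervals AGO2 intervals (`gene`, `start`, `end`).
#' @param stats Per-gene DE statistics (`gene`, `comparison`, `log2fc`,
#'   `p_value`) for comparisons `KO_vs_WT_Treg` and `Treg_vs_Teff`.
#' @param fold_threshold,alpha,adjust Passed to [expression_filter()].
#' @param site_table Optional precomputed site table (`gene`, `start`,
#'   `end`, `match_class`), e.g. imported external predictor output,
#'   bypassing the built-in scanner.
#' @return List of class `"candidate_set"`: `genes` (sorted character
#'   vector) and `evidence` (per gene: `sites`, `ko_stat`, `treg_stat`).
#' @export
run_screen <- function(utrs, mirna, ago_intervals, stats,
                       fold_threshold = 2, alpha = 0.05, adjust = FALSE,
                       site_table = NULL) {
  if (is.null(site_table)) {
    sites <- do.call(rbind, lapply(names(utrs), function(g)
      scan_seed_sites(utrs[[g]], mirna, gene = g)))
    if (is.null(sites))
      sites <- data.frame(gene = character(), start = integer(),
                          end = integer(), match_class = character(),
                          ago_supported = logical(), stringsAsFactors = FALSE)
  } else {
    sites <- site_table
    sites$ago_supported <- NA
  }
  sites <- mark_ago_support(sites, ago_intervals)
  with_site <- unique(sites$gene[sites$ago_supported])

  ko_genes <- unique(stats$gene[stats$comparison == "KO_vs_WT_Treg"])
  tr_genes <- unique(stats$gene[stats$comparison == "Treg_vs_Teff"])
  half <- union(setdiff(ko_genes, tr_genes), setdiff(tr_genes, ko_genes))
  if (length(half) > 0L)
    warning(length(half), " gene(s) present in only one comparison were excluded: ",
            paste(utils::head(half, 5L), collapse = ", "),
            if (length(half) > 5L) ", ..." else "")

  filt <- function(comparison, direction) {
    if (!comparison %in% stats$comparison) return(character())
    expression_filter(stats, comparison, direction,
                      fold_threshold, alpha, adjust)
  }
  up_ko <- filt("KO_vs_WT_Treg", "up")
  dn_tr <- filt("Treg_vs_Teff", "down")
  genes <- sort(Reduce(intersect,
                       list(with_site, up_ko, dn_tr, intersect(ko_genes, tr_genes))))
  evidence <- lapply(genes, function(g) list(
    sites = sites[sites$gene == g & sites$ago_supported, , drop = FALSE],
    ko_stat = stats[stats$gene == g & stats$comparison == "KO_vs_WT_Treg", ,
                    drop = FALSE],
    treg_stat = stats[stats$gene == g & stats$comparison == "Treg_vs_Teff", ,
                      drop = FALSE]
  ))
  names(evidence) <- genes
  structure(list(genes = genes, evidence = evidence), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate miRNA target set:", length(x$genes), "gene(s)\n")
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Simple moderated differential expression for synthetic data
#'
#' A deterministic shrunken-variance two-sample test used to turn the
#' generator's expression matrices into per-gene statistics. Log2 fold
#' change is the log2 ratio of linear group means; the t-statistic is
#' computed on log2 data with per-gene variance shrunk toward the
#' pooled median variance (prior df `d0 = 4`), and referred to a t
#' distribution with `d + d0` degrees of freedom. This is a lightweight
#' engine for synthetic cohorts; studies with real microarray/RNA-Seq
#' data should supply statistics from a dedicated DE package instead.
#'
#' @param expr Numeric matrix, genes x samples, strictly positive.
#' @param group_labels Factor/character of length `ncol(expr)` with
#'   exactly two levels; the *first* level is the first-named condition
#'   (positive log2fc = higher there).
#' @param comparison Label stored in the output `comparison` column.
#' @return Data frame: `gene`, `comparison`, `log2fc`, `p_value`.
#' @export
simple_moderated_de <- function(expr, group_labels, comparison = "A_vs_B") {
  stopifnot(is.matrix(expr), all(expr > 0))
  g <- factor(group_labels, levels = unique(as.character(group_labels)))
  if (nlevels(g) != 2L) stop("group_labels must have exactly two levels")
  n1 <- sum(g == levels(g)[1L]); n2 <- sum(g == levels(g)[2L])
  if (n1 < 2L || n2 < 2L)
    stop("Each group needs >= 2 samples (got ", n1, " and ", n2, ")")
  a <- expr[, g == levels(g)[1L], drop = FALSE]
  b <- expr[, g == levels(g)[2L], drop = FALSE]
  log2fc <- log2(rowMeans(a) / rowMeans(b))

  la <- log2(a); lb <- log2(b)
  d <- (n1 - 1L) + (n2 - 1L)
  s2 <- (apply(la, 1L, stats::var) * (n1 - 1L) +
         apply(lb, 1L, stats::var) * (n2 - 1L)) / d
  d0 <- 4
  s2_0 <- stats::median(s2)
  s2_post <- (d0 * s2_0 + d * s2) / (d0 + d)
  tstat <- (rowMeans(la) - rowMeans(lb)) / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tstat), df = d + d0, lower.tail = FALSE)
  data.frame(gene = rownames(expr), comparison = comparison,
             log2fc = log2fc, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}
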