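#' @title Synthetic-data generators with serialized ground truth
#' @description Every pipeline stage can be exercised offline on data
#'   whose truth is known by construction. One integer seed drives
#'   hierarchical substreams (a fixed offset per generator), so each
#'   module's fixtures can be regenerated independently and identically.
#' @name synthetic_data
NULL

# Deterministic substream seed, kept below 2^31.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 94906265) * 22 + offset)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic enhancer landscape with planted super-enhancers
#'
#' Emulates a hockey-stick enhancer signal distribution: `n_background`
#' regions draw signal from a light-tailed positive law (uniform on
#' 0.5--1.5 signal units) and `n_super` planted super-enhancers sit at
#' `super_fold` times the background median, spread over a further
#' 1--1.7x so their ranks are unambiguous. Regions are laid out on one
#' chromosome with inter-region gaps exceeding the stitch window; each
#' region comprises 1--3 constituent peaks within the window. A query
#' miRNA-like locus is placed `locus_offset` bp upstream (on the plus
#' strand) of the planted super-enhancer destined for rank
#' `locus_rank`, mirroring the geometry of a miRNA gene flanking a
#' lineage-factor-bound super-enhancer.
#'
#' @param seed Integer seed.
#' @param n_background,n_super Region counts (`n_super < n_background`).
#' @param super_fold Planted-to-background median signal ratio (>= 5).
#' @param locus_rank Rank of the super-enhancer the locus flanks.
#' @param locus_offset Gap (bp) between that super-enhancer and the
#'   locus.
#' @param stitch_distance Stitch window the layout must respect.
#' @param out_dir Optional directory; when given, writes `peaks.bed`,
#'   `treatment.tsv`, `control.tsv`, `loci.bed` and `truth.json`.
#' @return List: `peaks` (constituent peak intervals), `treatment` /
#'   `control` (bedGraph-like per-bp density tables), `loci` (the query
#'   locus), `truth` (planted super region ids, their designed signals,
#'   locus geometry, seed).
#' @export
gen_enhancer_landscape <- function(seed, n_background = 300L, n_super = 10L,
                                   super_fold = 10, locus_rank = 5L,
                                   locus_offset = 2000L,
                                   stitch_distance = 12500L,
                                   out_dir = NULL) {
  stopifnot(n_super < n_background, super_fold >= 5,
            locus_rank >= 1L, locus_rank <= n_super)
  set.seed(substream_seed(seed, 101L))
  n <- n_background + n_super
  bg <- stats::runif(n_background, 0.5, 1.5)
  sup <- super_fold * stats::median(bg) *
    seq(1.7, 1, length.out = n_super)  # descending: index 1 => rank 1
  signals <- numeric(n)
  sup_pos <- sort(sample.int(n, n_super))
  signals[sup_pos] <- sup
  signals[-sup_pos] <- bg

  chrom <- "chr1"
  peaks <- list(); treat <- list(); ctrl <- list()
  region_span <- matrix(0, n, 2L)
  pos <- 10000
  ctrl_density <- 0.1
  for (i in seq_len(n)) {
    k <- sample(1:3, 1L)
    widths <- sample(500:2000, k, replace = TRUE)
    gaps <- if (k > 1L) sample(200:3000, k - 1L, replace = TRUE) else integer()
    starts <- pos + cumsum(c(0L, widths[-k] + gaps))
    ends <- starts + widths
    share <- signals[i] * widths / sum(widths)  # per-peak signal total
    peaks[[i]] <- data.frame(chrom = chrom, start = starts, end = ends,
                             stringsAsFactors = FALSE)
    treat[[i]] <- data.frame(chrom = chrom, start = starts, end = ends,
                             value = share / widths + ctrl_density,
                             stringsAsFactors = FALSE)
    ctrl[[i]] <- data.frame(chrom = chrom, start = starts, end = ends,
                            value = ctrl_density, stringsAsFactors = FALSE)
    region_span[i, ] <- c(starts[1L], ends[k])
    pos <- ends[k] + stitch_distance + sample(1000:20000, 1L)
  }
  peaks <- do.call(rbind, peaks)
  peaks$name <- sprintf("peak%04d", seq_len(nrow(peaks)))
  peaks$score <- 0; peaks$strand <- "*"

  region_ids <- sprintf("%s:%d-%d", chrom, region_span[, 1L], region_span[, 2L])
  target_region <- sup_pos[locus_rank]  # sup signals descend with index
  locus_start <- region_span[target_region, 2L] + locus_offset
  loci <- data.frame(chrom = chrom, start = locus_start,
                     end = locus_start + 100L, name = "mirna_locus",
                     score = 0, strand = "+", stringsAsFactors = FALSE)

  truth <- list(
    seed = seed,
    planted_supers = region_ids[sup_pos],
    planted_signals = signals[sup_pos],
    locus_rank = locus_rank,
    locus_offset = locus_offset,
    locus_super = region_ids[target_region]
  )
  out <- list(peaks = peaks, treatment = do.call(rbind, treat),
              control = do.call(rbind, ctrl), loci = loci, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(out$peaks, file.path(out_dir, "peaks.bed"))
    write_tsv(out$treatment, file.path(out_dir, "treatment.tsv"))
    write_tsv(out$control, file.path(out_dir, "control.tsv"))
    write_bed(out$loci, file.path(out_dir, "loci.bed"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Generate a synthetic target-screen cohort
#'
#' Builds the three evidence layers of the screen with known truth:
#' `n_planted` genes carry an embedded 8mer seed site inside an AGO
#' interval, are up-shifted in the knockout-vs-wild-type comparison and
#' down-shifted in the Treg-vs-Teff comparison (linear fold drawn from
#' `fold_range`); every decoy fails exactly one randomly chosen
#' criterion (site without AGO support, no knockout up-shift, or no
#' Treg down-shift) while satisfying the other two. Accidental seed
#' cores in random UTRs are scrubbed so site truth is exact.
#'
#' @param seed Integer seed.
#' @param n_genes,n_planted Cohort size and planted-target count.
#' @param fold_range Linear fold-change range for planted effects
#'   (strictly above 2).
#' @param n_reps Samples per group in each expression matrix.
#' @param sigma_log2 SD of log2-normal expression noise.
#' @param utr_length UTR length (nt).
#' @param mirna Mature miRNA sequence; a random 22-nt RNA is drawn when
#'   `NULL`.
#' @param out_dir Optional directory: writes `utrs.fa`, `ago.tsv`,
#'   `expr_ko_vs_wt.tsv`, `expr_treg_vs_teff.tsv`, `truth.json`.
#' @return List: `utrs` (named vector), `ago` (intervals), `expr_ko` /
#'   `expr_treg` (matrices with group attribute), `groups_ko` /
#'   `groups_treg`, `mirna`, `truth` (planted genes, site positions,
#'   folds, decoy failure modes).
#' @export
gen_screen_cohort <- function(seed, n_genes = 53L, n_planted = 3L,
                              fold_range = c(2.8, 4), n_reps = 4L,
                              sigma_log2 = 0.15, utr_length = 500L,
                              mirna = NULL, out_dir = NULL) {
  stopifnot(n_planted <= n_genes, all(fold_range > 2) || all(fold_range == 1),
            n_reps >= 2L)
  set.seed(substream_seed(seed, 202L))
  if (is.null(mirna)) mirna <- random_rna(22L)
  mi <- mature_mirna(mirna)
  core <- rna_revcomp(substr(mi$sequence, 2L, 7L))
  site7 <- rna_revcomp(substr(mi$sequence, 2L, 8L))  # 7mer-m8 span

  genes <- sprintf("gene%03d", seq_len(n_genes))
  planted <- sort(sample(genes, n_planted))
  decoys <- setdiff(genes, planted)
  failure <- sample(c("no_ago_site", "no_ko_up", "no_treg_down"),
                    length(decoys), replace = TRUE)
  names(failure) <- decoys

  scrub_core <- function(s) {
    repeat {
      hit <- regexpr(core, s, fixed = TRUE)
      if (hit == -1L) return(s)
      p <- as.integer(hit) + 3L
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
    }
  }
  utrs <- character(n_genes); names(utrs) <- genes
  site_pos <- integer(n_genes); names(site_pos) <- genes
  ago <- list()
  for (g in genes) {
    s <- scrub_core(random_rna(utr_length))
    embed <- !(g %in% decoys) || failure[[g]] != "none"
    # every gene gets an embedded site except truth does not require it;
    # all planted and all decoys carry a site, but only planted and the
    # expression-failing decoys get a covering AGO interval.
    p <- sample(seq(30L, utr_length - 40L), 1L)
    site <- paste0(site7, "A")                    # 8mer site, span p..p+7
    substr(s, p, p + 7L) <- site
    s <- paste0(substr(s, 1L, p + 7L), scrub_core(substr(s, p + 8L, utr_length)))
    s <- paste0(scrub_core(substr(s, 1L, p - 1L)), substr(s, p, utr_length))
    utrs[[g]] <- s
    site_pos[[g]] <- p
    covered <- !(g %in% decoys) || failure[[g]] != "no_ago_site"
    if (covered) {
      ago[[length(ago) + 1L]] <- data.frame(
        gene = g, start = max(1L, p - 10L),
        end = min(utr_length, p + 17L), stringsAsFactors = FALSE)
    }
  }
  ago <- if (length(ago)) do.call(rbind, ago) else
    data.frame(gene = character(), start = integer(), end = integer())

  base <- stats::rlnorm(n_genes, log(100), 0.5); names(base) <- genes
  fold <- stats::runif(n_genes, fold_range[1L], fold_range[2L])
  names(fold) <- genes
  noise <- function(nr, nc) matrix(2^stats::rnorm(nr * nc, 0, sigma_log2), nr, nc)

  ko_up <- vapply(genes, function(g)
    !(g %in% decoys) || failure[[g]] != "no_ko_up", logical(1L))
  tr_dn <- vapply(genes, function(g)
    !(g %in% decoys) || failure[[g]] != "no_treg_down", logical(1L))

  mk <- function(mean1, mean2) {
    m <- cbind(matrix(rep(mean1, n_reps), ncol = n_reps),
               matrix(rep(mean2, n_reps), ncol = n_reps)) *
      noise(n_genes, 2L * n_reps)
    rownames(m) <- genes
    m
  }
  expr_ko <- mk(base * ifelse(ko_up, fold, 1), base)   # KO samples, then WT
  colnames(expr_ko) <- c(sprintf("KO_%d", seq_len(n_reps)),
                         sprintf("WT_%d", seq_len(n_reps)))
  expr_treg <- mk(base * ifelse(tr_dn, 1 / fold, 1), base)  # Treg, then Teff
  colnames(expr_treg) <- c(sprintf("Treg_%d", seq_len(n_reps)),
                           sprintf("Teff_%d", seq_len(n_reps)))

  truth <- list(
    seed = seed,
    planted_targets = planted,
    planted_sites = as.list(site_pos[planted]),
    planted_folds = as.list(round(fold[planted], 4L)),
    decoy_failure = as.list(failure),
    mirna = mi$sequence
  )
  out <- list(utrs = utrs, ago = ago,
              expr_ko = expr_ko,
              groups_ko = rep(c("KO", "WT"), each = n_reps),
              expr_treg = expr_treg,
              groups_treg = rep(c("Treg", "Teff"), each = n_reps),
              mirna = mi$sequence, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$utrs, file.path(out_dir, "utrs.fa"))
    write_tsv(out$ago, file.path(out_dir, "ago.tsv"))
    write_tsv(data.frame(gene = genes, out$expr_ko, check.names = FALSE),
              file.path(out_dir, "expr_ko_vs_wt.tsv"))
    write_tsv(data.frame(gene = genes, out$expr_treg, check.names = FALSE),
              file.path(out_dir, "expr_treg_vs_teff.tsv"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Compute screen-ready DE statistics from a generated cohort
#'
#' Applies [simple_moderated_de()] to both expression matrices of a
#' [gen_screen_cohort()] result, labeled with the two comparisons the
#' screen expects.
#'
#' @param cohort Result of [gen_screen_cohort()].
#' @return Data frame of per-gene statistics for both comparisons.
#' @export
cohort_de_stats <- function(cohort) {
  rbind(
    simple_moderated_de(cohort$expr_ko, cohort$groups_ko, "KO_vs_WT_Treg"),
    simple_moderated_de(cohort$expr_treg, cohort$groups_treg, "Treg_vs_Teff")
  )
}

# Percent of precursors dividing >= once under a Poisson division
# number truncated at max_generations.
truncated_poisson_pd <- function(lambda, max_generations = 8L) {
  if (lambda == 0) return(0)
  100 * (1 - stats::dpois(0L, lambda) / stats::ppois(max_generations, lambda))
}

#' Generate synthetic dye-dilution suppression-assay wells
#'
#' Emulates a Teff:Treg coculture titration read out by dye dilution:
#' in each well every precursor divides `k ~ Poisson(division_rate *
#' theta(ratio))` times (truncated at `max_generations`), yielding
#' `2^k` cells whose fluorescence is log-normal around
#' `gen0_center / 2^k`. `theta` is the per-ratio division-rate
#' multiplier encoding Treg potency (1 = no suppression); the default
#' `theta(r) = r/(r+2)` gives strong suppression at 1:1 that decays as
#' Tregs are diluted out toward 32:1. The true suppression statistic
#' per ratio is computed analytically from the truncated-Poisson
#' percent-divided values and stored in the truth bundle. An undivided
#' time-0 calibration well (`condition = "undivided"`) is always
#' emitted so the generation-0 center can be calibrated from data.
#'
#' @param seed Integer seed.
#' @param n_precursors Precursors seeded per well.
#' @param division_rate Poisson mean division number without Tregs.
#' @param ratios Teff:Treg ratios (numeric; 1 means 1:1).
#' @param suppression_theta Named numeric vector (names = ratios) or
#'   function of ratio giving the division-rate multiplier; `NULL` for
#'   the default curve.
#' @param cv_log SD of log10 fluorescence around each generation center.
#' @param gen0_center Undivided-peak fluorescence.
#' @param max_generations Division cap.
#' @param n_reps Replicate wells per condition (triplicate by default).
#' @param out_dir Optional directory: writes `events.csv`, `wells.csv`,
#'   `truth.json`.
#' @return List: `events` (`well_id`, `fluorescence`), `wells`
#'   (metadata), `truth` (`true_suppression` per ratio, `true_pd`,
#'   `true_precursors`, `gen0_center`, `theta`).
#' @export
gen_dilution_wells <- function(seed, n_precursors = 1000L, division_rate = 2.5,
                               ratios = c(1, 2, 4, 8, 16, 32),
                               suppression_theta = NULL, cv_log = 0.05,
                               gen0_center = 10000, max_generations = 8L,
                               n_reps = 3L, out_dir = NULL) {
  stopifnot(n_precursors >= 1L, division_rate >= 0, cv_log > 0)
  set.seed(substream_seed(seed, 303L))
  theta_of <- if (is.function(suppression_theta)) suppression_theta
    else if (is.null(suppression_theta)) function(r) r / (r + 2)
    else function(r) unname(suppression_theta[as.character(r)])

  gens <- 0:max_generations
  sim_well <- function(lambda, well_id) {
    pk <- if (lambda == 0) rep(0L, n_precursors) else
      sample(gens, n_precursors, replace = TRUE,
             prob = stats::dpois(gens, lambda))
    k <- rep(gens, tabulate(pk + 1L, length(gens)) * 2^gens)
    f <- gen0_center / 2^k * 10^stats::rnorm(length(k), 0, cv_log)
    data.frame(well_id = well_id, fluorescence = f, stringsAsFactors = FALSE)
  }

  wells <- rbind(
    data.frame(well_id = "undivided_t0", condition = "undivided",
               ratio = NA_real_, replicate = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(well_id = sprintf("teff_alone_r%d", seq_len(n_reps)),
               condition = "teff_alone", ratio = NA_real_,
               replicate = seq_len(n_reps), stringsAsFactors = FALSE),
    do.call(rbind, lapply(ratios, function(r)
      data.frame(well_id = sprintf("cc_%g_r%d", r, seq_len(n_reps)),
                 condition = "coculture", ratio = r,
                 replicate = seq_len(n_reps), stringsAsFactors = FALSE)))
  )
  events <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    lam <- switch(wells$condition[i],
                  undivided = 0,
                  teff_alone = division_rate,
                  coculture = division_rate * theta_of(wells$ratio[i]))
    sim_well(lam, wells$well_id[i])
  }))

  pd_ref <- truncated_poisson_pd(division_rate, max_generations)
  theta <- vapply(ratios, theta_of, numeric(1L))
  pd_cc <- vapply(division_rate * theta, truncated_poisson_pd,
                  numeric(1L), max_generations)
  truth <- list(
    seed = seed,
    gen0_center = gen0_center,
    true_precursors = n_precursors,
    theta = as.list(stats::setNames(theta, ratios)),
    true_pd = as.list(stats::setNames(c(pd_ref, pd_cc), c("teff_alone", ratios))),
    true_suppression = as.list(stats::setNames(100 * (1 - pd_cc / pd_ref), ratios))
  )
  out <- list(events = events, wells = wells, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(wells, file.path(out_dir, "wells.csv"), row.names = FALSE)
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Generate synthetic reporter wells
#'
#' Emulates the paired-construct reporter experiment: per construct,
#' empty-vector wells have NGFR/Thy1.1 ratios around `base_ratio`, and
#' miRNA-vector wells are scaled by `1 - repression` for that
#' construct, with multiplicative log-normal noise of coefficient of
#' variation `noise_cv` on each well.
#'
#' @param seed Integer seed.
#' @param repression_wt,repression_mut Repression fractions in \[0, 1\]
#'   for the wild-type and seed-mutant UTR constructs.
#' @param n_reps Wells per construct x vector group (quadruplicate by
#'   default).
#' @param noise_cv Multiplicative noise CV (0 = noiseless).
#' @param base_ratio Empty-vector NGFR/Thy1.1 ratio.
#' @param thy_mfi Transfection-control MFI level.
#' @param out_dir Optional directory: writes `reporter_wells.csv`,
#'   `truth.json`.
#' @return List: `wells` (data frame ready for
#'   [normalize_reporter()]), `truth` (per-construct repression).
#' @export
gen_reporter_wells <- function(seed, repression_wt = 0.6, repression_mut = 0,
                               n_reps = 4L, noise_cv = 0.1, base_ratio = 2,
                               thy_mfi = 200, out_dir = NULL) {
  stopifnot(repression_wt >= 0, repression_wt <= 1,
            repression_mut >= 0, repression_mut <= 1, n_reps >= 1L)
  set.seed(substream_seed(seed, 404L))
  repression <- c(wt_utr = repression_wt, mut_utr = repression_mut)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- list()
  for (con in names(repression)) {
    for (vec in c("empty", "mir_expressing")) {
      scale <- if (vec == "mir_expressing") 1 - repression[[con]] else 1
      ratio <- base_ratio * scale *
        (if (sdlog > 0) stats::rlnorm(n_reps, -sdlog^2 / 2, sdlog) else rep(1, n_reps))
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("%s_%s_r%d", con, vec, seq_len(n_reps)),
        construct = con, vector = vec,
        ngfr_mfi = ratio * thy_mfi, thy_mfi = thy_mfi,
        stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  truth <- list(seed = seed, true_repression = as.list(repression),
                base_ratio = base_ratio)
  out <- list(wells = wells, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(wells, file.path(out_dir, "reporter_wells.csv"),
                     row.names = FALSE)
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  out
}

# Serialize a truth bundle next to its dataset.
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
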