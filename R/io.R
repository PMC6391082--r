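#' Read genomic intervals from a BED file
#'
#' Reads 3--6 column BED into a data frame of 0-based half-open
#' intervals. Inputs recorded in 1-based closed coordinates (e.g. tables
#' transcribed from genome browsers) must be declared via
#' `convention = "one_based_closed"`; they are shifted on read so that
#' all in-memory coordinates share the single 0-based half-open
#' convention.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param convention Coordinate convention of the *file*:
#'   `"bed_0_half_open"` (default, standard BED) or
#'   `"one_based_closed"`.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`. Missing name/score/strand columns are filled
#'   with `"."`, `0` and `"*"` (unstranded).
#' @export
read_bed <- function(path, convention = c("bed_0_half_open", "one_based_closed")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(raw) < 3L) stop("BED file must have at least 3 columns: ", path)
  df <- data.frame(
    chrom  = raw[[1L]],
    start  = suppressWarnings(as.numeric(raw[[2L]])),
    end    = suppressWarnings(as.numeric(raw[[3L]])),
    name   = if (ncol(raw) >= 4L) raw[[4L]] else ".",
    score  = if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5L]])) else 0,
    strand = if (ncol(raw) >= 6L) raw[[6L]] else "*",
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1L]
    stop("Non-numeric coordinates in BED file at line ", bad, ": ", path)
  }
  if (convention == "one_based_closed") {
    df$start <- df$start - 1  # end stays: 1-based closed end == half-open end
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L) {
    stop("Invalid interval (start >= end) in ", path, " at line ", bad[1L])
  }
  if (any(!nzchar(df$chrom))) stop("Empty chromosome name in ", path)
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  df
}

#' Write genomic intervals to a BED file
#'
#' Inverse of [read_bed()] under the default convention: writes 6-column
#' BED (0-based half-open), deterministically ordered as given.
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom  = intervals$chrom,
    start  = format_number(intervals$start),
    end    = format_number(intervals$end),
    name   = if (!is.null(intervals$name)) intervals$name else ".",
    score  = if (!is.null(intervals$score)) format_number(intervals$score) else "0",
    strand = if (!is.null(intervals$strand)) intervals$strand else "*",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 3' UTR (or any) sequences from FASTA
#'
#' Wraps [Biostrings::readBStringSet()]. Record ids are the first
#' whitespace-delimited header token; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, one element
#'   per record, names = gene identifiers.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("Duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Fixed 6-significant-digit float formatting so every writer is
# byte-deterministic given its input. Integers print without decimals.
format_number <- function(x) {
  out <- character(length(x))
  int <- !is.na(x) & (x == round(x)) & abs(x) < 1e15
  out[int] <- format(round(x[int]), scientific = FALSE, trim = TRUE)
  out[!int] <- formatC(signif(x[!int], 6L), format = "g", digits = 6L)
  out[is.na(x)] <- "NA"
  out
}

#' Write a data frame as a deterministic TSV
#'
#' All tabular outputs use tab separation, a header line, and fixed
#' 6-significant-digit float formatting, so identical inputs produce
#' byte-identical files.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_number(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Default run configuration
#'
#' Central bundle of the pipeline's tunable thresholds. Every analysis
#' entry point takes its defaults from here so one config object fully
#' determines a run.
#'
#' @param seed Integer seed driving all synthetic generation.
#' @return A list with class `"tregmir_config"`: coordinate convention,
#'   fold-change and significance thresholds, stitch distance,
#'   generation cap, miRNA sequence slot and log level.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    coordinate_convention = "bed_0_half_open",
    fold_threshold  = 2,
    alpha           = 0.05,
    stitch_distance = 12500L,
    max_generations = 8L,
    mirna_sequence  = NA_character_,  # supplied by the user; never hard-coded
    seed            = as.integer(seed),
    log_level       = "info"
  ), class = "tregmir_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "tregmir_config"))
  with(config, {
    if (!coordinate_convention %in% c("bed_0_half_open", "one_based_closed"))
      stop("Unknown coordinate convention: ", coordinate_convention)
    if (fold_threshold < 1) stop("fold_threshold must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (stitch_distance < 0) stop("stitch_distance must be non-negative")
    if (max_generations < 1) stop("max_generations must be >= 1")
  })
  invisible(config)
}

#' Save / load a run configuration as YAML
#'
#' Round-trip stable: `load_config(save_config(cfg, path))` equals `cfg`.
#'
#' @param config A `tregmir_config` list from [default_config()].
#' @param path YAML file path.
#' @return `save_config`: `path` invisibly; `load_config`: the config.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$stitch_distance <- as.integer(cfg$stitch_distance)
  cfg$max_generations <- as.integer(cfg$max_generations)
  validate_config(cfg)
  cfg
}

# Stage-prefixed logging to stderr; warnings are counted by the caller
# that assembles the run report.
log_msg <- function(stage, ..., level = "info") {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
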