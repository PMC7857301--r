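# Tab-separated output with byte-stable formatting, and VCF export.

fmtNum <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%d", as.integer(x)), sprintf("%.6g", x)))
}

.genStatsCols <- c("replicate", "generation", "phase", "N", "K", "mean_het",
                   "mean_Froh", "mean_fitness", "n_weak", "n_moderate",
                   "n_strong", "n_very_strong")

#' Write per-generation summary statistics
#'
#' Tab-separated file with the columns replicate, generation, phase, N, K,
#' mean_het, mean_Froh, mean_fitness, n_weak, n_moderate, n_strong,
#' n_very_strong (the deleterious-allele bins ordered weak, moderate,
#' strong, very strong). Numbers are written with 6 significant digits so
#' repeated runs with the same seed produce byte-identical files.
#'
#' @param records GenStats data.frame (one row per recorded generation).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readGenStats()]
#' @export
writeGenStats <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("no records to write", call. = FALSE)
  stopifnot(all(.genStatsCols %in% names(records)))
  df <- records[, .genStatsCols]
  out <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(fmtNum(df$replicate[i]), fmtNum(df$generation[i]),
            as.character(df$phase[i]), fmtNum(df$N[i]), fmtNum(df$K[i]),
            vapply(df[i, 6:12], fmtNum, character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(paste(.genStatsCols, collapse = "\t"), out), path)
  invisible(path)
}

#' @rdname writeGenStats
#' @export
readGenStats <- function(path) {
  read.delim(path, colClasses = c(phase = "character"))
}

#' Write the extinction summary
#'
#' One row per replicate: replicate, scenario, extinction_generation
#' (generations since the final contraction, or max_generations when
#' censored), censored flag, number of rescue events, and the rescue-event
#' generations as a semicolon-separated list.
#'
#' @param extinctions extinction data.frame from [runReplicates()].
#' @param path output path.
#' @param rescue_events optional rescue-event data.frame.
#' @return `path`, invisibly.
#' @export
writeExtinctions <- function(extinctions, path, rescue_events = NULL) {
  if (is.null(extinctions) || nrow(extinctions) == 0)
    stop("no records to write", call. = FALSE)
  gens <- vapply(extinctions$replicate, function(r) {
    if (is.null(rescue_events) || !nrow(rescue_events)) return("")
    paste(rescue_events$generation[rescue_events$replicate == r],
          collapse = ";")
  }, character(1))
  df <- data.frame(replicate = extinctions$replicate,
                   scenario = extinctions$scenario,
                   extinction_generation = extinctions$extinction_generation,
                   censored = ifelse(extinctions$censored, "TRUE", "FALSE"),
                   n_rescue_events = extinctions$n_rescue_events,
                   rescue_generations = gens)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExtinctions
#' @export
readExtinctions <- function(path) {
  df <- read.delim(path, colClasses = c(rescue_generations = "character"))
  df$censored <- as.logical(df$censored)
  df
}

#' Export sampled genotypes as VCF
#'
#' Writes a VCF 4.2 file with one record per mutation carried by at least
#' one sampled individual. CHROM is the chromosome label, POS the 1-based
#' position on the chromosome's coding coordinate, and INFO carries the
#' selection (`S=`) and dominance (`H=`) coefficients; genotypes are
#' unphased diploid GT fields.
#'
#' @param pop a [Population-class].
#' @param idx indices of the individuals to export.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportVCF <- function(pop, idx, path) {
  if (!length(idx)) stop("empty sample", call. = FALSE)
  genos <- getGenotypes(pop)[idx]
  tab <- mutationTable(pop)
  ids <- individualIds(pop)[idx]
  present <- sort(unique(unlist(lapply(genos, unlist), use.names = FALSE)))

  counts <- chromGeneCounts(pop@map)
  L <- pop@map@geneLength
  chromStartGene <- cumsum(c(0L, counts))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rescueSim",
    sprintf("##contig=<ID=chr%d,length=%d>", seq_along(counts), counts * L),
    "##INFO=<ID=S,Number=1,Type=Float,Description=\"Selection coefficient\">",
    "##INFO=<ID=H,Number=1,Type=Float,Description=\"Dominance coefficient\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", ids)), collapse = "\t"))
  if (!length(present)) {
    writeLines(header, path)
    return(invisible(path))
  }

  sub <- tab[present, ]
  local_pos <- sub$pos - chromStartGene[sub$chrom] * L
  ord <- order(sub$chrom, local_pos, sub$id)
  sub <- sub[ord, ]
  local_pos <- local_pos[ord]
  gt <- vapply(genos, function(g) {
    a <- as.integer(sub$id %in% g$h1)
    b <- as.integer(sub$id %in% g$h2)
    paste0(pmin(a, b), "/", pmax(a, b))
  }, character(nrow(sub)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(sub))
  body <- vapply(seq_len(nrow(sub)), function(i) {
    paste(c(paste0("chr", sub$chrom[i]), local_pos[i], sub$id[i], "A", "T",
            ".", "PASS",
            sprintf("S=%.6g;H=%.6g", sub$s[i], sub$h[i]), "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
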