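#' Read a TSS table
#'
#' @param path TSV with columns chrom, position, strand, category, gene_id.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "position", "strand", "category", "gene_id")
  if (!all(need %in% colnames(df)))
    stopf("TSS table must have columns: %s", paste(need, collapse = ", "))
  if (any(df$position < 1)) stopf("TSS position must be >= 1")
  ok <- c("primary", "secondary", "internal", "antisense", "orphan")
  if (any(!df$category %in% ok))
    stopf("unknown TSS category: %s",
          paste(setdiff(unique(df$category), ok), collapse = ", "))
  df
}

#' Keep only primary TSS
#'
#' @param records TSS data.frame.
#' @return subset with category == "primary", order preserved.
#' @export
filter_primary_tss <- function(records) {
  records[records$category == "primary", , drop = FALSE]
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract strand-aware TSS-anchored promoter windows
#'
#' Offsets are TSS-relative with the TSS itself at 0 and both ends
#' inclusive, so (-20, 0) yields a 21-nt window; minus-strand windows are
#' reverse-complemented so that the returned sequence reads 5'->3' on the
#' gene's strand. Windows extending past a contig end are skipped with a
#' warning.
#'
#' @param tss TSS data.frame (chrom, position, strand, gene_id, ...).
#' @param genome `DNAStringSet` (or named character) of contigs.
#' @param from_off,to_off inclusive TSS-relative offsets (from_off <
#'   to_off; default -20..0, the extended -10 region).
#' @return data.frame: gene_id, chrom, position, strand, from_off, to_off,
#'   sequence (uppercase character).
#' @export
extract_windows <- function(tss, genome, from_off = -20L, to_off = 0L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (from_off >= to_off) stopf("from_off must be < to_off")
  if (any(!tss$chrom %in% names(genome)))
    stopf("TSS chromosome(s) not in genome: %s",
          paste(setdiff(unique(tss$chrom), names(genome)), collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  lo <- ifelse(tss$strand == "+", tss$position + from_off,
               tss$position - to_off)
  hi <- ifelse(tss$strand == "+", tss$position + to_off,
               tss$position - from_off)
  ok <- lo >= 1 & hi <= lens[tss$chrom]
  if (any(!ok))
    warning(sprintf("skipping %d TSS with out-of-contig windows", sum(!ok)))
  tss <- tss[ok, , drop = FALSE]
  lo <- lo[ok]; hi <- hi[ok]
  if (nrow(tss) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      position = numeric(0), strand = character(0),
                      from_off = integer(0), to_off = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  seqs <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    s <- Biostrings::subseq(genome[[tss$chrom[i]]], lo[i], hi[i])
    if (tss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
             position = tss$position, strand = tss$strand,
             from_off = from_off, to_off = to_off, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", N = "[ACGT]", R = "[AG]",
           Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]")
  chars <- strsplit(toupper(motif), "")[[1]]
  if (any(!chars %in% names(map))) stopf("unsupported motif symbol")
  paste(map[chars], collapse = "")
}

#' @keywords internal
#' @noRd
enumerate_hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  do.call(expand.grid,
          c(rep(list(bases), 6), stringsAsFactors = FALSE))
}

#' Anchor a -10 motif inside promoter windows
#'
#' Two modes. Pattern mode (`motif` a 6-symbol IUPAC string, default
#' "TANNNT"): the leftmost match in each window becomes the anchor.
#' PWM mode (`motif` a 4 x 6 matrix with rows A, C, G, T of position
#' weights): every offset is scored by summed log-weights, the best-scoring
#' position is taken, and its exact P-value is the probability, under the
#' background base distribution, that a random hexamer scores at least as
#' high — computed by full enumeration of all 4096 hexamers; anchors with
#' P >= `p_max` are dropped. Windows without a qualifying site are dropped
#' in both modes.
#'
#' @param windows data.frame from [extract_windows()].
#' @param motif IUPAC string of length 6 or a 4 x 6 numeric matrix.
#' @param p_max PWM-mode P-value cutoff (default 0.05).
#' @param background base probabilities (A, C, G, T) for the PWM-mode
#'   P-value; default uniform.
#' @return `windows` subset with extra columns `anchor_index` (1-based
#'   position in the window), `anchor_offset` (TSS-relative offset of the
#'   motif start), `site` (the 6-mer), and `p_value` (PWM mode only).
#' @export
scan_motif <- function(windows, motif = "TANNNT", p_max = 0.05,
                       background = c(A = 0.25, C = 0.25, G = 0.25,
                                      T = 0.25)) {
  if (is.matrix(motif)) {
    if (!all(dim(motif) == c(4, 6)) || any(motif < 0) || any(!is.finite(motif)))
      stopf("PWM must be a non-negative 4 x 6 matrix (rows A, C, G, T)")
    rownames(motif) <- c("A", "C", "G", "T")
    logw <- log(motif + 1e-12)
    base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
    score_hex <- function(chars) {
      sum(logw[cbind(base_idx[chars], 1:6)])
    }
    hex <- enumerate_hexamers()
    hex_scores <- apply(as.matrix(hex), 1, score_hex)
    hex_prob <- apply(as.matrix(hex), 1, function(ch)
      prod(background[ch]))
    res <- lapply(seq_len(nrow(windows)), function(i) {
      w <- strsplit(windows$sequence[i], "")[[1]]
      npos <- length(w) - 5L
      if (npos < 1) return(NULL)
      scores <- vapply(seq_len(npos), function(j) score_hex(w[j:(j + 5L)]),
                       numeric(1))
      best <- which.max(scores)
      pv <- sum(hex_prob[hex_scores >= scores[best] - 1e-12])
      if (pv >= p_max) return(NULL)
      cbind(windows[i, , drop = FALSE],
            data.frame(anchor_index = best,
                       anchor_offset = windows$from_off[i] + best - 1L,
                       site = paste(w[best:(best + 5L)], collapse = ""),
                       p_value = pv, stringsAsFactors = FALSE))
    })
  } else {
    if (nchar(motif) != 6) stopf("motif must have 6 positions")
    rx <- iupac_regex(motif)
    res <- lapply(seq_len(nrow(windows)), function(i) {
      m <- regexpr(rx, windows$sequence[i])
      if (m < 0) return(NULL)
      idx <- as.integer(m)
      cbind(windows[i, , drop = FALSE],
            data.frame(anchor_index = idx,
                       anchor_offset = windows$from_off[i] + idx - 1L,
                       site = substr(windows$sequence[i], idx, idx + 5L),
                       p_value = NA_real_, stringsAsFactors = FALSE))
    })
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- cbind(windows[0, , drop = FALSE],
                 data.frame(anchor_index = integer(0),
                            anchor_offset = integer(0), site = character(0),
                            p_value = numeric(0)))
  rownames(out) <- NULL
  out
}

#' Classify anchored sites by the -14/-13 dinucleotide
#'
#' The two bases immediately 5' of the anchored -10 element (nominal
#' offsets -14 and -13 when the motif anchors at -12) decide the class:
#' `GG` (both G), `G` (exactly one G), `noG` (no G). Sites whose anchor
#' sits fewer than 2 positions into the window are skipped with a message.
#' The base at the anchor position itself (nominal -12) is tallied too.
#'
#' @param sites data.frame from [scan_motif()].
#' @return list: `sites` (with `gg_class` and `base_at_minus12` columns),
#'   `counts` (named GG/G/noG), `base_at_minus12` (A/C/G/T tally over
#'   anchor-position bases), `n_sites`, `n_skipped`.
#' @export
classify_gg <- function(sites) {
  keep <- sites$anchor_index >= 3L
  if (any(!keep))
    message(sprintf("classify_gg: skipped %d site(s) with anchor too close to the window edge",
                    sum(!keep)))
  s <- sites[keep, , drop = FALSE]
  di <- substr(s$sequence, s$anchor_index - 2L, s$anchor_index - 1L)
  n_g <- vapply(strsplit(di, ""), function(x) sum(x == "G"), integer(1))
  s$gg_class <- c("noG", "G", "GG")[n_g + 1L]
  s$base_at_minus12 <- substr(s$site, 1L, 1L)
  counts <- vapply(c("GG", "G", "noG"), function(k) sum(s$gg_class == k),
                   integer(1))
  base_tab <- vapply(c("A", "C", "G", "T"),
                     function(b) sum(s$base_at_minus12 == b), integer(1))
  list(sites = s, counts = counts, base_at_minus12 = base_tab,
       n_sites = nrow(s), n_skipped = sum(!keep))
}

#' Genome-wide GG dinucleotide frequency
#'
#' Overlapping occurrences of GG summed over all contigs, divided by the
#' total number of dinucleotide positions, sum(length - 1). Single strand,
#' as given; set `both_strands = TRUE` to average with the reverse
#' complement (CC on the given strand has the same count as GG on the
#' other, so the pooled frequency is (count GG + count CC) / (2 sum(len-1))).
#'
#' @param genome `DNAStringSet` or character vector of contig sequences.
#' @param both_strands count both strands (default FALSE).
#' @return frequency in \[0, 1\].
#' @export
genome_gg_frequency <- function(genome, both_strands = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stopf("empty genome")
  widths <- Biostrings::width(genome)
  if (any(widths < 2)) stopf("contig shorter than 2 bp")
  gg <- sum(Biostrings::vcountPattern("GG", genome))
  denom <- sum(widths - 1)
  if (!both_strands) return(gg / denom)
  cc <- sum(Biostrings::vcountPattern("CC", genome))
  (gg + cc) / (2 * denom)
}

#' Expected number of GG-bearing sites under the genome background
#'
#' @param f_gg genome GG frequency in \[0, 1\].
#' @param n_sites number of analyzed sites (>= 0).
#' @return list: `raw` = f_gg * n_sites, `rounded`.
#' @export
expected_gg_sites <- function(f_gg, n_sites) {
  assert_scalar_num(f_gg, "f_gg", lo = 0, hi = 1)
  assert_scalar_num(n_sites, "n_sites", lo = 0)
  raw <- f_gg * n_sites
  list(raw = raw, rounded = round(raw))
}

#' Fisher exact test for GG enrichment
#'
#' 2 x 2 table: (dependent, independent) x (GG, not GG).
#'
#' @param dep_gg,dep_not counts in the regulator-dependent promoter class.
#' @param ind_gg,ind_not counts in the independent class.
#' @param alternative passed to [stats::fisher.test()]; two-sided default.
#' @return the Fisher exact P-value.
#' @export
fisher_gg_enrichment <- function(dep_gg, dep_not, ind_gg, ind_not,
                                 alternative = "two.sided") {
  counts <- c(dep_gg, dep_not, ind_gg, ind_not)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (sum(counts) == 0) stopf("all-zero contingency table")
  m <- matrix(counts, nrow = 2, byrow = TRUE,
              dimnames = list(c("dependent", "independent"),
                              c("GG", "notGG")))
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' End-to-end promoter -10/GG report
#'
#' Filters primary TSS, splits them into regulator-dependent and
#' independent sets, extracts -20..0 windows, anchors the motif, classifies
#' the -14/-13 dinucleotide, and tests GG enrichment of the dependent class
#' against the independent class. The expected GG count uses the
#' genome-wide GG frequency.
#'
#' @param genome `DNAStringSet` or named character contigs.
#' @param tss TSS data.frame.
#' @param dependent_genes character vector of regulon gene ids.
#' @param motif passed to [scan_motif()].
#' @return list: per-class site tables and counts, `f_gg`, `expected_gg`
#'   (for the dependent site count), and `fisher_p`.
#' @export
promoter_gg_report <- function(genome, tss, dependent_genes,
                               motif = "TANNNT") {
  prim <- filter_primary_tss(tss)
  dep_tss <- prim[prim$gene_id %in% dependent_genes, , drop = FALSE]
  ind_tss <- prim[!prim$gene_id %in% dependent_genes, , drop = FALSE]
  one_class <- function(t) {
    if (nrow(t) == 0)
      return(list(counts = c(GG = 0L, G = 0L, noG = 0L), n_sites = 0L,
                  sites = NULL))
    w <- extract_windows(t, genome)
    classify_gg(scan_motif(w, motif))
  }
  dep <- one_class(dep_tss)
  ind <- one_class(ind_tss)
  f_gg <- genome_gg_frequency(genome)
  fisher_p <- if (dep$n_sites > 0 && ind$n_sites > 0)
    fisher_gg_enrichment(dep$counts[["GG"]],
                         dep$n_sites - dep$counts[["GG"]],
                         ind$counts[["GG"]],
                         ind$n_sites - ind$counts[["GG"]]) else NA_real_
  list(dependent = dep, independent = ind, f_gg = f_gg,
       expected_gg = expected_gg_sites(f_gg, dep$n_sites),
       fisher_p = fisher_p)
}
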