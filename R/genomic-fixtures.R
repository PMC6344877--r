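# Toy-genome fixture generation: a single contig with evenly slotted genes,
# each owning its upstream region, so planted TSS, peaks and -10 motifs never
# collide across genes. All coordinates are 1-based inclusive.

#' @keywords internal
#' @noRd
revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

# genome position of a TSS-relative offset (negative = upstream)
#' @keywords internal
#' @noRd
offset_pos <- function(tss_pos, strand, offset) {
  if (strand == "+") tss_pos + offset else tss_pos - offset
}

# read genome bases at TSS-relative offsets o1..o2, 5'->3' on the TSS strand
#' @keywords internal
#' @noRd
read_offsets <- function(genome_chars, tss_pos, strand, o1, o2) {
  if (strand == "+") {
    genome_chars[(tss_pos + o1):(tss_pos + o2)]
  } else {
    revcomp_chars(genome_chars[(tss_pos - o2):(tss_pos - o1)])
  }
}

# write bases (5'->3' on the TSS strand) at TSS-relative offsets o1..o2
#' @keywords internal
#' @noRd
write_offsets <- function(genome_chars, tss_pos, strand, o1, seq_chars) {
  o2 <- o1 + length(seq_chars) - 1L
  if (strand == "+") {
    genome_chars[(tss_pos + o1):(tss_pos + o2)] <- seq_chars
  } else {
    genome_chars[(tss_pos - o2):(tss_pos - o1)] <- revcomp_chars(seq_chars)
  }
  genome_chars
}

#' @keywords internal
#' @noRd
find_tannnt <- function(window_chars) {
  n <- length(window_chars)
  hits <- integer(0)
  for (i in seq_len(n - 5L)) {
    if (window_chars[i] == "T" && window_chars[i + 1L] == "A" &&
        window_chars[i + 5L] == "T")
      hits <- c(hits, i)
  }
  hits
}

#' Generate a mutually consistent toy-genome fixture bundle
#'
#' Builds a random high-GC contig and plants, with known ground truth:
#' genes (CDS plus a few structural RNAs) with strand and start codon
#' position; operon membership; one TSS per gene (mostly category
#' "primary"); ChIP peaks whose summits sit at chosen distances upstream of
#' start codons, split into filter-passing assignable peaks, passing peaks
#' beyond the assignment cutoff, and peaks failing the P/fold-enrichment
#' filter; and TANNNT -10 elements at TSS offsets -12..-7 with controlled
#' GG/G/noG dinucleotide classes at offsets -14/-13. Windows of primary TSS
#' are scrubbed so their leftmost TANNNT match is exactly the planted one.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character, one contig), `genes`,
#'   `operons`, `tss`, `peaks` data.frames, and `truth` (list of
#'   `regulon`, `peaks`, `promoters` data.frames), plus the `config`.
#' @export
make_genomic_fixtures <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  n <- config$n_genomic_genes
  slot <- L %/% n
  if (slot < 1200)
    stopf("genome_length too small for %d genes (need >= %d bp)", n, 1200 * n)
  set.seed(derive_seed(config$seed, "genome"))
  gc <- config$gc_fraction
  genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  chrom <- "toy_chr"

  # --- genes -----------------------------------------------------------
  anchors <- (seq_len(n) - 1L) * slot + 500L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gene_len <- 600L
  n_srna <- max(1L, round(0.10 * n))
  n_trna <- max(1L, round(0.05 * n))
  types <- c(rep("sRNA", n_srna), rep("tRNA", n_trna), "rRNA", "misc_RNA")
  types <- c(types, rep("CDS", n - length(types)))
  types <- sample(types)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom, strand = strands,
    start_codon_pos = anchors, feature_type = types,
    start = ifelse(strands == "+", anchors, pmax(1L, anchors - gene_len + 1L)),
    end = ifelse(strands == "+", pmin(L, anchors + gene_len - 1L), anchors),
    stringsAsFactors = FALSE)

  # --- operons: consecutive same-strand CDS genes, size 2-3 -------------
  operons <- list()
  op_id <- 0L
  i <- 1L
  while (i <= n - 1L) {
    run <- i
    while (length(run) < 3L && max(run) < n &&
           genes$feature_type[max(run) + 1L] == "CDS" &&
           genes$feature_type[i] == "CDS" &&
           genes$strand[max(run) + 1L] == genes$strand[i])
      run <- c(run, max(run) + 1L)
    if (length(run) >= 2L && runif(1) < 0.5) {
      op_id <- op_id + 1L
      operons[[op_id]] <- data.frame(
        operon_id = sprintf("op%02d", op_id),
        gene_id = genes$gene_id[run], rank = seq_along(run),
        stringsAsFactors = FALSE)
      i <- max(run) + 1L
    } else {
      i <- i + 1L
    }
  }
  operons <- if (length(operons)) do.call(rbind, operons) else
    data.frame(operon_id = character(0), gene_id = character(0),
               rank = integer(0))
  genes$operon_id <- operons$operon_id[match(genes$gene_id, operons$gene_id)]

  # --- peaks ------------------------------------------------------------
  n_bound <- floor(config$bound_fraction * n)
  bound_idx <- sort(sample(n, n_bound))
  free_idx <- setdiff(seq_len(n), bound_idx)
  n_far <- min(config$n_far_peaks, length(free_idx))
  far_idx <- if (n_far > 0) sort(sample(free_idx, n_far)) else integer(0)
  rest_idx <- setdiff(free_idx, far_idx)
  n_weak <- min(config$n_weak_peaks, length(rest_idx))
  weak_idx <- if (n_weak > 0) sort(sample(rest_idx, n_weak)) else integer(0)

  mk_peaks <- function(idx, dist_range, passing, label) {
    if (length(idx) == 0) return(NULL)
    d <- round(runif(length(idx), dist_range[1], dist_range[2]))
    summit <- ifelse(genes$strand[idx] == "+",
                     genes$start_codon_pos[idx] - d,
                     genes$start_codon_pos[idx] + d)
    if (passing) {
      p <- 10^runif(length(idx), -6, -2)
      fe <- runif(length(idx), 2.5, 8)
    } else {
      fail_fe <- runif(length(idx)) < 0.5
      p <- ifelse(fail_fe, 10^runif(length(idx), -6, -2),
                  runif(length(idx), 0.06, 0.5))
      fe <- ifelse(fail_fe, runif(length(idx), 1.0, 1.9),
                   runif(length(idx), 2.5, 8))
    }
    data.frame(gene_id = genes$gene_id[idx], distance = d, summit = summit,
               p_value = p, fold_enrichment = fe, class = label,
               stringsAsFactors = FALSE)
  }
  peak_truth <- rbind(
    mk_peaks(bound_idx, config$peak_distance_range, TRUE, "assignable"),
    mk_peaks(far_idx, config$far_peak_distance_range, TRUE, "too_far"),
    mk_peaks(weak_idx, config$peak_distance_range, FALSE, "filtered_out"))
  peak_truth$passes_filter <- peak_truth$class != "filtered_out"
  peak_truth$assignable <- peak_truth$distance <= 300
  peak_truth$name <- sprintf("peak_%02d", seq_len(nrow(peak_truth)))
  peaks <- data.frame(
    chrom = chrom,
    start = pmax(1L, peak_truth$summit - 75L),
    end = pmin(L, peak_truth$summit + 75L),
    summit = peak_truth$summit,
    neg_log10_pvalue = -log10(peak_truth$p_value),
    fold_enrichment = peak_truth$fold_enrichment,
    name = peak_truth$name, stringsAsFactors = FALSE)

  # regulon truth: directly bound genes, expanded over their operons
  direct_genes <- genes$gene_id[bound_idx]
  op_of_direct <- unique(stats::na.omit(genes$operon_id[bound_idx]))
  operon_members <- operons$gene_id[operons$operon_id %in% op_of_direct]
  regulon_genes <- union(direct_genes, operon_members)
  truth_regulon <- data.frame(
    gene_id = regulon_genes,
    direct = regulon_genes %in% direct_genes,
    via_operon = regulon_genes %in% setdiff(operon_members, direct_genes),
    stringsAsFactors = FALSE)

  # --- TSS and -10 motif planting --------------------------------------
  d_tss <- round(runif(n, 40, 150))
  tss_pos <- ifelse(strands == "+", anchors - d_tss, anchors + d_tss)
  category <- ifelse(runif(n) < 0.8, "primary",
                     sample(c("secondary", "internal"), n, replace = TRUE))
  tss <- data.frame(chrom = chrom, position = tss_pos, strand = strands,
                    category = category, gene_id = genes$gene_id,
                    stringsAsFactors = FALSE)

  dependent <- genes$gene_id %in% regulon_genes
  prom <- vector("list", n)
  for (i in seq_len(n)) {
    planted <- FALSE
    gg_class <- NA_character_
    if (category[i] == "primary" && runif(1) < config$motif_plant_rate) {
      planted <- TRUE
      motif <- c("T", "A",
                 sample(c("A", "C", "G", "T"), 3, replace = TRUE), "T")
      genome <- write_offsets(genome, tss_pos[i], strands[i], -12L, motif)
      rate <- if (dependent[i]) config$gg_rate_dependent else
        config$gg_rate_independent
      if (runif(1) < rate) {
        dinuc <- c("G", "G")
      } else {
        repeat {
          dinuc <- sample(c("A", "C", "G", "T"), 2, replace = TRUE,
                          prob = c(0.14, 0.36, 0.36, 0.14))
          if (!all(dinuc == "G")) break
        }
      }
      genome <- write_offsets(genome, tss_pos[i], strands[i], -14L, dinuc)
      gg_class <- if (all(dinuc == "G")) "GG" else
        if (any(dinuc == "G")) "G" else "noG"
    }
    prom[[i]] <- data.frame(gene_id = genes$gene_id[i],
                            tss_pos = tss_pos[i], strand = strands[i],
                            category = category[i], dependent = dependent[i],
                            motif_planted = planted, gg_class = gg_class,
                            anchor_offset = if (planted) -12L else NA_integer_,
                            stringsAsFactors = FALSE)
  }
  truth_promoters <- do.call(rbind, prom)

  # scrub stray TANNNT so the leftmost window match equals the planted one
  for (i in seq_len(n)) {
    if (category[i] != "primary") next
    for (attempt in 1:20) {
      win <- read_offsets(genome, tss_pos[i], strands[i], -20L, 0L)
      hits <- find_tannnt(win)
      planted_at <- if (truth_promoters$motif_planted[i]) 9L else NA_integer_
      stray <- if (is.na(planted_at)) hits else hits[hits < planted_at]
      if (length(stray) == 0) break
      if (attempt == 20) stopf("could not scrub stray motif near %s",
                               genes$gene_id[i])
      off <- -21L + stray[1]  # window index 1 is offset -20
      genome <- write_offsets(genome, tss_pos[i], strands[i], off, "C")
    }
  }

  genome_seq <- paste(genome, collapse = "")
  names(genome_seq) <- chrom
  list(genome = genome_seq,
       genes = genes[, c("gene_id", "chrom", "strand", "start", "end",
                         "start_codon_pos", "feature_type", "operon_id")],
       operons = operons, tss = tss, peaks = peaks,
       truth = list(regulon = truth_regulon, peaks = peak_truth,
                    promoters = truth_promoters),
       config = config)
}

#' Write a fixture bundle to disk as plain-text files
#'
#' Emits genome.fasta, genes.gff3, tss.tsv, peaks.tsv, operons.tsv and
#' truth_*.tsv into `outdir`.
#'
#' @param fx result of [make_genomic_fixtures()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_genomic_fixtures <- function(fx, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fasta"),
             genes = file.path(outdir, "genes.gff3"),
             tss = file.path(outdir, "tss.tsv"),
             peaks = file.path(outdir, "peaks.tsv"),
             operons = file.path(outdir, "operons.tsv"),
             truth_regulon = file.path(outdir, "truth_regulon.tsv"),
             truth_peaks = file.path(outdir, "truth_peaks.tsv"),
             truth_promoters = file.path(outdir, "truth_promoters.tsv"))
  dna <- Biostrings::DNAStringSet(fx$genome)
  Biostrings::writeXStringSet(dna, paths[["genome"]])

  g <- fx$genes
  attrs <- sprintf("ID=%s;feature_type=%s%s", g$gene_id, g$feature_type,
                   ifelse(is.na(g$operon_id), "",
                          paste0(";operon_id=", g$operon_id)))
  gff <- data.frame(g$chrom, "regulonkin", "gene", g$start, g$end, ".",
                    g$strand, ".", attrs)
  con <- file(paths[["genes"]], "w")
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)

  write_tsv(fx$tss, paths[["tss"]])
  write_tsv(fx$peaks, paths[["peaks"]])
  write_tsv(fx$operons, paths[["operons"]])
  write_tsv(fx$truth$regulon, paths[["truth_regulon"]])
  write_tsv(fx$truth$peaks, paths[["truth_peaks"]])
  write_tsv(fx$truth$promoters, paths[["truth_promoters"]])
  invisible(paths)
}
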