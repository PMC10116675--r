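# Seeded simulator of labelled pileups: genuine variants plus four artefact
# classes, including library-preparation artefacts that are reproduced in
# context tracks sharing the preparation and are invisible from the
# tumour/germline pair alone.

#' Simulation configuration
#'
#' Distributions the pileup simulator draws from. Reads per track are
#' Poisson around `coverage_mean`; read lengths Poisson around
#' `read_length` (floored at 8); base and mapping qualities are normal,
#' rounded and clipped to their phred ranges. `vaf` is the target
#' alt-allele fraction carried by a genuine variant's tumour pileup.
#' `artefact_mix` gives the class proportions used by [generate_dataset()]
#' for the artefact half of a mixture.
#'
#' @param coverage_mean mean reads per track overlapping the window
#' @param read_length mean read length in bases
#' @param vaf target variant allele frequency in (0, 1\]
#' @param error_rate per-base sequencing error probability
#' @param base_qual_mean,base_qual_sd,base_qual_max base-quality profile
#' @param map_qual_mean,map_qual_sd,map_qual_max mapping-quality profile
#' @param noise_qual_mean mean quality of noise-artefact alt bases
#' @param noise_rate per-read probability of a scattered noise alt call
#' @param artefact_mix named proportions over the four artefact classes
#'   (must sum to 1)
#' @param context_shares_prep do the context tracks share the tumour's
#'   library preparation (so preparation artefacts reappear in them)?
#' @param seed optional default seed recorded with generated datasets
#' @return object of class `sim_config`
#' @export
sim_config <- function(coverage_mean = 80, read_length = 100, vaf = 0.4,
                       error_rate = 0.005,
                       base_qual_mean = 35, base_qual_sd = 3,
                       base_qual_max = 41,
                       map_qual_mean = 55, map_qual_sd = 5,
                       map_qual_max = 60,
                       noise_qual_mean = 12, noise_rate = 0.08,
                       artefact_mix = c(strand_bias = 0.2,
                                        low_complexity_misalignment = 0.2,
                                        random_noise = 0.2,
                                        library_prep = 0.4),
                       context_shares_prep = TRUE, seed = NULL) {
  if (vaf <= 0 || vaf > 1) stop_usage("vaf must lie in (0, 1]")
  if (abs(sum(artefact_mix) - 1) > 1e-8)
    stop_usage("artefact_mix proportions must sum to 1")
  need <- c("strand_bias", "low_complexity_misalignment", "random_noise",
            "library_prep")
  if (!setequal(names(artefact_mix), need))
    stop_usage("artefact_mix must name exactly the classes: ",
               paste(need, collapse = ", "))
  structure(list(coverage_mean = coverage_mean, read_length = read_length,
                 vaf = vaf, error_rate = error_rate,
                 base_qual_mean = base_qual_mean, base_qual_sd = base_qual_sd,
                 base_qual_max = base_qual_max,
                 map_qual_mean = map_qual_mean, map_qual_sd = map_qual_sd,
                 map_qual_max = map_qual_max,
                 noise_qual_mean = noise_qual_mean, noise_rate = noise_rate,
                 artefact_mix = artefact_mix[need],
                 context_shares_prep = isTRUE(context_shares_prep),
                 seed = seed),
            class = "sim_config")
}

#' Artefact classes known to the simulator
#' @return character vector of the four class names
#' @export
artefact_classes <- function() {
  c("strand_bias", "low_complexity_misalignment", "random_noise",
    "library_prep")
}

sim_quals <- function(n, mean, sd, qmax) {
  pmax(2L, pmin(as.integer(qmax), as.integer(round(rnorm(n, mean, sd)))))
}

# one track's reads over the window around pos0 (0-based locus).
# alt injection: reads covering the locus carry alt_base w.p. p_alt,
# optionally restricted to one strand, with degraded quality, or with
# misalignment features (short reads, noisy neighbourhood, low mapq).
sim_track_reads <- function(chrom, ref, pos0, cfg, enc, track_tag,
                            alt_base = NULL, p_alt = 0, strand_only = NA,
                            alt_low_qual = FALSE, misalign = FALSE) {
  half <- (enc$d_window - 1L) %/% 2L
  win0 <- pos0 - half
  win1 <- pos0 + half
  n <- rpois(1, cfg$coverage_mean)
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    L <- max(8L, as.integer(rpois(1, cfg$read_length)))
    rev <- runif(1) < 0.5
    start0 <- as.integer(floor(runif(1, win0 - L + 1, win1 + 1)))
    covers <- start0 <= pos0 && pos0 < start0 + L
    is_alt <- FALSE
    if (covers && !is.null(alt_base)) {
      eligible <- is.na(strand_only) || identical(rev, strand_only)
      if (eligible && runif(1) < p_alt) is_alt <- TRUE
    }
    if (is_alt && misalign) {  # misaligned support: short, locus-covering
      L <- max(8L, L %/% 2L)
      start0 <- max(start0, pos0 - L + 1L)
      start0 <- min(start0, pos0)
    }
    start0 <- max(0L, min(start0, length(ref) - L))
    bases <- ref[start0 + seq_len(L)]
    quals <- sim_quals(L, cfg$base_qual_mean, cfg$base_qual_sd,
                       cfg$base_qual_max)
    err <- runif(L) < cfg$error_rate
    if (any(err)) {
      bases[err] <- vapply(bases[err], function(b)
        sample(setdiff(BASES, b), 1), character(1))
      # miscalled bases carry low phred quality, as the basecaller flags them
      quals[err] <- sim_quals(sum(err), cfg$noise_qual_mean, 3,
                              cfg$base_qual_max)
    }
    mapq <- max(0L, min(as.integer(cfg$map_qual_max),
                        as.integer(round(rnorm(1, cfg$map_qual_mean,
                                               cfg$map_qual_sd)))))
    if (is_alt) {
      at <- pos0 - start0 + 1L
      bases[at] <- alt_base
      if (alt_low_qual)
        quals[at] <- sim_quals(1, cfg$noise_qual_mean, 3, cfg$base_qual_max)
      if (misalign) {
        neigh <- abs(start0 + seq_len(L) - 1L - pos0) <= 5L
        quals[neigh] <- pmax(2L, quals[neigh] - 12L)
        extra <- neigh & runif(L) < 0.05
        if (any(extra))
          bases[extra] <- vapply(bases[extra], function(b)
            sample(setdiff(BASES, b), 1), character(1))
        mapq <- max(0L, mapq - 20L)
      }
    }
    reads[[i]] <- aligned_read(qname = sprintf("%s_r%04d", track_tag, i),
                               chrom = chrom, start = start0, bases = bases,
                               quals = quals, mapq = mapq, is_reverse = rev)
  }
  reads
}

sim_site <- function(chrom, cfg, enc) {
  half <- (enc$d_window - 1L) %/% 2L
  margin <- 4L * max(8L, as.integer(cfg$read_length))
  ref_len <- enc$d_window + 2L * margin
  ref <- sample(BASES, ref_len, replace = TRUE)
  pos1 <- margin + half + 1L        # 1-based locus
  ref_base <- ref[pos1]
  alt_base <- sample(setdiff(BASES, ref_base), 1)
  list(ref = ref, pos1 = pos1,
       site = candidate_site(chrom, pos1, ref_base, alt_base,
                             mutation_class = sample(default_mutation_classes(), 1),
                             vaf = cfg$vaf))
}

encode_tracks <- function(track_reads, site, enc, label, keep_reads, ref) {
  tensors <- lapply(track_reads, function(reads) {
    win <- extract_window(read_set(reads), site, enc)
    encode_track(win, site, enc)
  })
  out <- assemble_composite(tensors$germline, tensors$tumour,
                            tensors[grep("^context_", names(tensors))],
                            site = site, config = enc, label = label)
  if (keep_reads) {
    out$reads <- track_reads
    out$ref <- paste(ref, collapse = "")
  }
  out
}

#' Simulate a genuine somatic variant
#'
#' The tumour track carries the alternative base in approximately `vaf` of
#' its locus-covering reads (independent Bernoulli per read); germline and
#' context tracks show the alternative only at the sequencing-error rate.
#'
#' @param config a [sim_config()]
#' @param enc an [encoding_config()]
#' @param seed optional seed (bit-reproducible output for a fixed seed)
#' @param chrom contig name for the simulated site
#' @param keep_reads retain the underlying reads and reference sequence
#'   (needed for BAM/VCF fixture export)
#' @return a `composite_sample` with label "mutation"
#' @export
generate_true_variant <- function(config = sim_config(),
                                  enc = encoding_config(), seed = NULL,
                                  chrom = "sim", keep_reads = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ss <- sim_site(chrom, config, enc)
  pos0 <- ss$pos1 - 1L
  alt <- ss$site$alt_base
  tracks <- c("germline", "tumour",
              if (enc$n_context > 0) paste0("context_", seq_len(enc$n_context)))
  track_reads <- setNames(lapply(tracks, function(tr) {
    if (tr == "tumour")
      sim_track_reads(chrom, ss$ref, pos0, config, enc, tr,
                      alt_base = alt, p_alt = config$vaf)
    else
      sim_track_reads(chrom, ss$ref, pos0, config, enc, tr)
  }), tracks)
  ss$site$label <- "mutation"
  encode_tracks(track_reads, ss$site, enc, "mutation", keep_reads, ss$ref)
}

#' Simulate a sequencing artefact
#'
#' Four classes are modelled. `strand_bias`: alternative support confined
#' to one read direction. `low_complexity_misalignment`: the locus sits in
#' a low-complexity stretch and alternative support rides on short,
#' low-mapping-quality reads with degraded base qualities and extra errors
#' near the locus. `random_noise`: scattered low-quality alternative calls
#' at the noise rate, with no consistent variant signal.
#' `library_prep`: alternative support at the target VAF in the tumour
#' *and* in every context track sharing the library preparation, absent
#' from the germline — indistinguishable from a genuine variant when only
#' tumour and germline are inspected.
#'
#' @param artefact_class one of [artefact_classes()]
#' @inheritParams generate_true_variant
#' @return a `composite_sample` with label "artefact"
#' @export
generate_artifact <- function(artefact_class, config = sim_config(),
                              enc = encoding_config(), seed = NULL,
                              chrom = "sim", keep_reads = FALSE) {
  if (!artefact_class %in% artefact_classes())
    stop_usage("unknown artefact class '", artefact_class, "'; must be one of ",
               paste(artefact_classes(), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  ss <- sim_site(chrom, config, enc)
  if (artefact_class == "low_complexity_misalignment") {
    # plant the locus inside a dinucleotide repeat, keeping ref/alt valid
    unit <- c(ss$site$ref_base, sample(setdiff(BASES, ss$site$ref_base), 1))
    span <- (ss$pos1 - 10L):(ss$pos1 + 10L)
    ss$ref[span] <- rep_len(unit, length(span))
    ss$ref[ss$pos1] <- ss$site$ref_base
  }
  pos0 <- ss$pos1 - 1L
  alt <- ss$site$alt_base
  vaf <- config$vaf
  tumour_args <- switch(artefact_class,
    strand_bias = list(alt_base = alt, p_alt = min(1, 2 * vaf),
                       strand_only = runif(1) < 0.5),
    low_complexity_misalignment = list(alt_base = alt, p_alt = vaf,
                                       misalign = TRUE),
    random_noise = list(alt_base = alt, p_alt = config$noise_rate,
                        alt_low_qual = TRUE),
    library_prep = list(alt_base = alt, p_alt = vaf))
  context_args <- if (artefact_class == "library_prep" &&
                      config$context_shares_prep)
    list(alt_base = alt, p_alt = vaf) else list()
  tracks <- c("germline", "tumour",
              if (enc$n_context > 0) paste0("context_", seq_len(enc$n_context)))
  track_reads <- setNames(lapply(tracks, function(tr) {
    args <- c(list(chrom = chrom, ref = ss$ref, pos0 = pos0, cfg = config,
                   enc = enc, track_tag = tr),
              if (tr == "tumour") tumour_args
              else if (grepl("^context_", tr)) context_args)
    do.call(sim_track_reads, args)
  }), tracks)
  ss$site$label <- "artefact"
  out <- encode_tracks(track_reads, ss$site, enc, "artefact", keep_reads,
                       ss$ref)
  out$artefact_class <- artefact_class
  out
}

#' Simulate a labelled dataset of composite samples
#'
#' Produces a reproducible mixture of genuine variants and artefacts with
#' deterministic class allocation: exactly `round(n * p_mutation)` samples
#' are labelled "mutation" and the artefact remainder follows
#' `config$artefact_mix` by largest remainder. Each site lives on its own
#' contig so exported fixtures are self-contained.
#'
#' @param n number of samples
#' @param p_mutation fraction of genuine variants
#' @param config a [sim_config()]
#' @param enc an [encoding_config()]
#' @param seed RNG seed (same seed, same dataset, bit for bit)
#' @param keep_reads retain reads/reference per sample for fixture export
#' @return object of class `labelled_dataset`: list with `samples`, `meta`
#'   (one row per sample: chrom, pos, ref_base, alt_base, label,
#'   artefact_class, vaf, mutation_class), `config`, `encoding`, `seed`
#' @export
generate_dataset <- function(n, p_mutation = 0.5, config = sim_config(),
                             enc = encoding_config(), seed = NULL,
                             keep_reads = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_mut <- as.integer(round_half_up(n * p_mutation))
  n_art <- n - n_mut
  mix <- config$artefact_mix
  art_counts <- floor(mix * n_art)
  rem <- n_art - sum(art_counts)
  if (rem > 0) {
    frac <- mix * n_art - art_counts
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    art_counts[bump] <- art_counts[bump] + 1
  }
  kinds <- c(rep("mutation", n_mut),
             rep(names(art_counts), times = art_counts))
  kinds <- kinds[sample.int(n)]  # interleave deterministically under seed
  samples <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    chrom <- sprintf("s%05d", i)
    s <- if (kinds[i] == "mutation")
      generate_true_variant(config, enc, chrom = chrom, keep_reads = keep_reads)
    else
      generate_artifact(kinds[i], config, enc, chrom = chrom,
                        keep_reads = keep_reads)
    samples[[i]] <- s
    meta[[i]] <- data.frame(
      id = i, chrom = chrom, pos = s$site$pos, ref_base = s$site$ref_base,
      alt_base = s$site$alt_base, label = s$label,
      artefact_class = if (kinds[i] == "mutation") NA_character_ else kinds[i],
      vaf = config$vaf, mutation_class = s$site$mutation_class,
      stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, meta = do.call(rbind, meta),
                 config = config, encoding = enc, seed = seed),
            class = "labelled_dataset")
}

#' @export
length.labelled_dataset <- function(x) length(x$samples)

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d samples (%d mutation / %d artefact), shape (%s)\n",
              length(x$samples), sum(x$meta$label == "mutation"),
              sum(x$meta$label == "artefact"),
              paste(dim(x$samples[[1]]$values), collapse = "x")))
  invisible(x)
}

#' Drop context tracks from every sample of a dataset
#'
#' @param ds a `labelled_dataset`
#' @return the dataset with all samples reduced to germline + tumour
#' @export
strip_context_dataset <- function(ds) {
  ds$samples <- lapply(ds$samples, strip_context)
  ds$encoding$n_context <- 0L
  ds
}

#' Export a simulated dataset as BAM/VCF/FASTA fixtures
#'
#' Writes a synthetic reference FASTA (one contig per site), one
#' coordinate-sorted and indexed BAM per track, a candidate VCF annotated
#' with the functional class and target VAF, a label sidecar TSV, and a
#' YAML file mapping each track to its library-preparation batch. The
#' dataset must have been generated with `keep_reads = TRUE`.
#'
#' @param ds a `labelled_dataset` with retained reads
#' @param dir output directory (created if missing)
#' @return named list of written paths (`reference`, `bams`, `vcf`,
#'   `labels`, `config`)
#' @export
write_dataset_fixtures <- function(ds, dir) {
  if (is.null(ds$samples[[1]]$reads))
    stop_usage("dataset was generated without keep_reads = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- ds$meta$chrom
  refs <- vapply(ds$samples, `[[`, character(1), "ref")
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(refs, contigs)), fa)

  tracks <- ds$samples[[1]]$tracks
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", contigs, nchar(refs))
  bams <- setNames(vector("list", length(tracks)), tracks)
  for (tr in tracks) {
    lines <- c("@HD\tVN:1.6\tSO:unsorted", sq)
    for (i in seq_along(ds$samples)) {
      for (rd in ds$samples[[i]]$reads[[tr]]) {
        lines <- c(lines, sprintf(
          "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          paste0(contigs[i], "_", rd$qname),
          if (rd$is_reverse) 16L else 0L,
          contigs[i], rd$start + 1L, rd$mapq, rd$cigar,
          paste(rd$bases, collapse = ""),
          intToUtf8(rd$quals + 33L)))
      }
    }
    sam <- file.path(dir, paste0(tr, ".sam"))
    writeLines(lines, sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, tr), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    bams[[tr]] <- bam
  }

  vcf <- file.path(dir, "candidates.vcf")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs, nchar(refs)),
    "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Target variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tFunc.refGene=%s;VAF=%g",
            ds$meta$chrom, ds$meta$pos, ds$meta$ref_base, ds$meta$alt_base,
            ds$meta$mutation_class, ds$meta$vaf))
  writeLines(vcf_lines, vcf)

  labels <- file.path(dir, "labels.tsv")
  lab <- ds$meta[, c("chrom", "pos", "ref_base", "alt_base", "label")]
  names(lab) <- c("chrom", "pos", "ref", "alt", "label")
  write.table(lab, labels, sep = "\t", quote = FALSE, row.names = FALSE)

  cfgfile <- file.path(dir, "config.yaml")
  batches <- setNames(as.list(c("prep1",
                                rep("prep2", length(tracks) - 1))), tracks)
  if (!ds$config$context_shares_prep)
    batches[grep("^context_", tracks)] <- "prep3"
  yaml::write_yaml(list(batches = batches,
                        sim_config = unclass(ds$config)[setdiff(names(unclass(ds$config)), "artefact_mix")],
                        artefact_mix = as.list(ds$config$artefact_mix),
                        encoding = unclass(ds$encoding),
                        seed = ds$seed), cfgfile)

  list(reference = fa, bams = unlist(bams), vcf = vcf, labels = labels,
       config = cfgfile)
}

#' Pick context tracks sharing a library preparation
#'
#' Given a sample-to-batch mapping (e.g. read from the YAML written by
#' [write_dataset_fixtures()]), selects `n` tracks from the tumour's batch,
#' excluding the tumour and germline themselves, uniformly at random under
#' the seed.
#'
#' @param batches named list or vector mapping track ids to batch ids
#' @param tumour id of the tumour track
#' @param n number of context tracks wanted
#' @param exclude additional ids to exclude (e.g. the germline)
#' @param seed optional seed for the draw
#' @return character vector of n selected track ids
#' @export
pick_context_tracks <- function(batches, tumour, n, exclude = character(),
                                seed = NULL) {
  b <- unlist(batches)
  if (!tumour %in% names(b)) stop_data("tumour track '", tumour, "' not in metadata")
  pool <- setdiff(names(b)[b == b[[tumour]]], c(tumour, exclude))
  if (length(pool) < n)
    stop_data("only ", length(pool), " track(s) share the preparation of '",
              tumour, "', need ", n)
  if (!is.null(seed)) set.seed(seed)
  sample(pool, n)
}
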