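#' Parameters for the synthetic miRNA-seq generator
#'
#' Defines a deterministic study: a miRBase-like reference with planted
#' structures (identical matures on different hairpins, a cluster of three
#' overlapping matures, a reverse-complementary 5p/3p arm pair, identical
#' hairpins), a small genome with decoy contigs, and multi-sample stranded
#' reads with isomiR end offsets, substitution errors, 3' adapters and
#' background noise.
#'
#' @param seed Integer seed; fixes all randomness of the generator.
#' @param n_hairpins Total hairpins, including the six structure-bearing ones
#'   (default 24).
#' @param hairpin_len Length range of ordinary hairpins in nt (default 70-90;
#'   structure-bearing hairpins use the upper bound).
#' @param mature_len Length range of ordinary mature arms (default 20-23 nt;
#'   planted structures use 22 nt).
#' @param n_samples,reads_per_sample Study size (default 8 x 50000).
#' @param offset5_probs,offset3_probs Named probability vectors over the 5'
#'   offset support `{-1,0,1}` and the 3' support `{-3..3}`; defaults are
#'   shaped so the 3' end varies much more than the seed-constrained 5' end.
#' @param error_rate Per-base substitution rate on the sequenced read
#'   (default 0.001, a typical Illumina substitution rate; must be `< 0.1`).
#'   Errors are drawn independently per base, so essentially every mismatch
#'   read is a sporadic singleton; real libraries additionally contain
#'   recurrent mismatch reads (SNPs, editing, cross-mapping) that an iid
#'   error model cannot produce.
#' @param adapter 3' adapter ligated to every insert (default the Illumina
#'   small-RNA adapter `TGGAATTCTCGGGTGCCAAGG`).
#' @param read_length Sequencer read length (default 50 nt; reads shorter than
#'   this after the adapter are padded with `A`).
#' @param noise_fraction Fraction of reads drawn from decoy genome contigs
#'   (default 0.05).
#' @param decoy_reads_per_sample Error-free reads emitted from the planted
#'   1-substitution decoy locus per sample (default 25); these align to a
#'   miRNA with one mismatch yet match the genome perfectly, so the remap
#'   step should invalidate every one of them.
#' @param n_decoys,decoy_len Plain decoy contigs in the genome (default 4 x
#'   500 nt).
#' @param trace_fraction Fraction of ordinary arms given sporadic trace
#'   abundance (default 0.25): present in a sample with probability
#'   `trace_presence` (default 0.3) at Poisson(`trace_mean`, default 1.5)
#'   copies. These emulate the sparse low-count reads the cross-sample noise
#'   filter targets.
#' @param trace_presence,trace_mean See `trace_fraction`.
#' @param abundance_sdlog Log-normal sd of the expression profile of the
#'   remaining entries (default 1.5).
#' @return List of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         n_hairpins = 24,
                         hairpin_len = c(70, 90),
                         mature_len = c(20, 23),
                         n_samples = 8,
                         reads_per_sample = 50000,
                         offset5_probs = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                         offset3_probs = c("-3" = 0.045, "-2" = 0.08, "-1" = 0.2,
                                           "0" = 0.35, "1" = 0.2, "2" = 0.08,
                                           "3" = 0.045),
                         error_rate = 0.001,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         read_length = 50,
                         noise_fraction = 0.05,
                         decoy_reads_per_sample = 25,
                         n_decoys = 4,
                         decoy_len = 500,
                         trace_fraction = 0.25,
                         trace_presence = 0.3,
                         trace_mean = 1.5,
                         abundance_sdlog = 1.5) {
  .check(abs(sum(offset5_probs) - 1) < 1e-8 && abs(sum(offset3_probs) - 1) < 1e-8,
         "offset probabilities must each sum to 1")
  .check(error_rate >= 0 && error_rate < 0.1, "error_rate must be in [0, 0.1)")
  .check(n_hairpins >= 6, "n_hairpins must be >= 6 to host the planted structures")
  .check(max(hairpin_len) >= 72, "hairpin_len upper bound must be >= 72")
  p <- list(seed = as.integer(seed), n_hairpins = n_hairpins,
            hairpin_len = hairpin_len, mature_len = mature_len,
            n_samples = n_samples, reads_per_sample = reads_per_sample,
            offset5_probs = offset5_probs, offset3_probs = offset3_probs,
            error_rate = error_rate, adapter = adapter,
            read_length = read_length, noise_fraction = noise_fraction,
            decoy_reads_per_sample = decoy_reads_per_sample,
            n_decoys = n_decoys, decoy_len = decoy_len,
            trace_fraction = trace_fraction, trace_presence = trace_presence,
            trace_mean = trace_mean, abundance_sdlog = abundance_sdlog)
  structure(p, class = "synth_params")
}

#' Generate a miRBase-like mature/hairpin reference with planted structures
#'
#' The first six hairpins carry, by construction: an identical mature shared
#' by two distinct hairpins (hp 1/2), one hairpin bearing three mutually
#' overlapping matures staggered by 8 nt (hp 3; with extension 4 and offsets
#' within the default supports, no read of one mature fits inside an
#' overlapping mature's extended segment, keeping per-mature attribution
#' unambiguous), a reverse-complementary 5p/3p arm pair on one hairpin
#' (hp 4), and a byte-identical hairpin pair (hp 5/6). The remaining hairpins
#' carry one or two non-overlapping arms.
#'
#' @param params A `synth_params` object.
#' @return List with `mature` and `hairpin` data.frames (`id`, `seq`, DNA
#'   alphabet) and a `manifest`: planted occurrences (`mature_id`,
#'   `hairpin_id`, `start`, `end`, 0-based half-open), `entry_of` (mature id
#'   -> quantification entry id, i.e. the smallest id of its
#'   identical-sequence group) and the planted `structures`.
#' @export
synth_reference <- function(params) {
  set.seed(params$seed)
  Lmax <- max(params$hairpin_len)
  hp_id <- sprintf("syn-mir-%03d", seq_len(params$n_hairpins))
  hp_seq <- character(params$n_hairpins)
  occ <- list()
  add_occ <- function(mid, hid, start, len) {
    occ[[length(occ) + 1L]] <<- data.frame(
      mature_id = mid, hairpin_id = hid, start = start, end = start + len,
      stringsAsFactors = FALSE)
  }
  # hp1/hp2: identical mature on two hairpins
  hp_seq[1] <- random_dna(1, Lmax)
  m_dup <- substr(hp_seq[1], 11, 32)
  hp_seq[2] <- random_dna(1, Lmax)
  substr(hp_seq[2], 21, 42) <- m_dup
  add_occ("syn-miR-001-5p", hp_id[1], 10L, 22L)
  add_occ("syn-miR-002-5p", hp_id[2], 20L, 22L)
  # hp3: three mutually overlapping matures, 8 nt stagger
  hp_seq[3] <- random_dna(1, Lmax)
  add_occ("syn-miR-003a", hp_id[3], 10L, 22L)
  add_occ("syn-miR-003b", hp_id[3], 18L, 22L)
  add_occ("syn-miR-003c", hp_id[3], 26L, 22L)
  # hp4: reverse-complementary 5p/3p arms
  hp_seq[4] <- random_dna(1, Lmax)
  arm5 <- random_dna(1, 22)
  substr(hp_seq[4], 11, 32) <- arm5
  substr(hp_seq[4], 45, 66) <- revcomp(arm5)
  add_occ("syn-miR-004-5p", hp_id[4], 10L, 22L)
  add_occ("syn-miR-004-3p", hp_id[4], 44L, 22L)
  # hp5/hp6: identical hairpins
  hp_seq[5] <- random_dna(1, Lmax)
  hp_seq[6] <- hp_seq[5]
  add_occ("syn-miR-005-5p", hp_id[5], 12L, 22L)
  add_occ("syn-miR-006-5p", hp_id[6], 12L, 22L)
  # ordinary hairpins: a 5p arm, and a 3p arm with probability 0.7
  for (i in seq(7, params$n_hairpins)) {
    L <- sample(seq(min(params$hairpin_len), Lmax), 1)
    hp_seq[i] <- random_dna(1, L)
    len5 <- sample(seq(min(params$mature_len), max(params$mature_len)), 1)
    add_occ(sprintf("syn-miR-%03d-5p", i), hp_id[i], 8L, len5)
    if (stats::runif(1) < 0.7) {
      len3 <- sample(seq(min(params$mature_len), max(params$mature_len)), 1)
      start3 <- 8L + len5 + 10L
      if (start3 + len3 + 6L <= L) {
        add_occ(sprintf("syn-miR-%03d-3p", i), hp_id[i], start3, len3)
      }
    }
  }
  occ <- do.call(rbind, occ)
  hp <- data.frame(id = hp_id, seq = hp_seq, stringsAsFactors = FALSE)
  hp_of <- stats::setNames(hp_seq, hp_id)
  occ$seq <- substr(hp_of[occ$hairpin_id], occ$start + 1L, occ$end)
  mature <- unique(occ[, c("mature_id", "seq")])
  .check(!anyDuplicated(mature$mature_id), "internal: duplicate mature id")
  # quantification entry of each mature = smallest id of its identical group
  entry_of <- unlist(lapply(split(mature$mature_id, mature$seq), function(ids) {
    stats::setNames(rep(min(ids), length(ids)), ids)
  }), use.names = TRUE)
  names(entry_of) <- sub("^.*\\.", "", names(entry_of))
  manifest <- list(
    occurrences = occ,
    entry_of = entry_of[mature$mature_id],
    structures = list(
      identical_matures = c("syn-miR-001-5p", "syn-miR-002-5p"),
      overlap_cluster = c("syn-miR-003a", "syn-miR-003b", "syn-miR-003c"),
      revcomp_pair = c("syn-miR-004-5p", "syn-miR-004-3p"),
      identical_hairpins = c(hp_id[5], hp_id[6])
    )
  )
  list(mature = data.frame(id = mature$mature_id, seq = mature$seq,
                           stringsAsFactors = FALSE),
       hairpin = hp, manifest = manifest)
}

#' Generate a small reference genome with decoy contigs
#'
#' The genome holds every hairpin locus embedded in random flanking sequence,
#' `n_decoys` random decoy contigs, and one decoy contig carrying a
#' single-substitution variant of a planted mature. Reads emitted from that
#' variant locus align to the miRNA reference with exactly one mismatch while
#' matching the genome perfectly -- the situation the remap-invalidation step
#' exists to catch.
#'
#' @param ref Reference from [synth_reference()].
#' @param params A `synth_params` object.
#' @return List with `contigs` (data.frame `id`, `seq`) and `variant`
#'   (`seq`, `source_mature`, `source_entry`).
#' @export
synth_genome <- function(ref, params) {
  set.seed((params$seed + 1L) %% .Machine$integer.max)
  hp <- ref$hairpin
  contigs <- data.frame(
    id = paste0("chr_", hp$id),
    seq = paste0(random_dna(nrow(hp), 30), hp$seq, random_dna(nrow(hp), 30)),
    stringsAsFactors = FALSE
  )
  if (params$n_decoys > 0) {
    contigs <- rbind(contigs, data.frame(
      id = sprintf("decoy_%02d", seq_len(params$n_decoys)),
      seq = random_dna(params$n_decoys, params$decoy_len),
      stringsAsFactors = FALSE))
  }
  src <- "syn-miR-007-5p"
  src_seq <- ref$mature$seq[ref$mature$id == src]
  .check(length(src_seq) == 1L, "internal: variant source mature missing")
  pos <- 11L
  old <- substr(src_seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  variant <- src_seq
  substr(variant, pos, pos) <- new
  contigs <- rbind(contigs, data.frame(
    id = "decoy_variant",
    seq = paste0(random_dna(1, 60), variant, random_dna(1, 60)),
    stringsAsFactors = FALSE))
  entry_of <- ref$manifest$entry_of
  list(contigs = contigs,
       variant = list(seq = variant, source_mature = src,
                      source_entry = unname(entry_of[src])))
}

#' Simulate multi-sample stranded miRNA-seq reads with ground truth
#'
#' Every miRNA read is a sense-strand hairpin substring at planted 5'/3'
#' offsets, with per-base substitution errors, the 3' adapter appended, and
#' padding/truncation to the read length. Background noise reads are drawn
#' from plain decoy contigs (either strand); planted decoy reads are exact
#' copies of the genome's variant mature. Read ids encode their provenance
#' (`mir|entry|o5|o3|sample|serial|e<n>`, `noise|contig|pos|strand|serial`,
#' `decoy|serial`) as a testing convenience; the pipeline never reads them.
#'
#' @param ref Reference from [synth_reference()].
#' @param genome Genome from [synth_genome()] (or `NULL` to disable noise and
#'   decoy reads).
#' @param params A `synth_params` object.
#' @return List with `reads` (named list per sample: character vector of read
#'   sequences), `ids` (matching read ids) and `truth` (data.frame: `sample`,
#'   `origin` in mirna/noise/decoy, `entry_id`, `offset5`, `offset3`,
#'   `n_err`, `n_err_insert`, `insert` -- the post-error insert sequence).
#' @export
simulate_reads <- function(ref, genome, params) {
  set.seed((params$seed + 2L) %% .Machine$integer.max)
  man <- ref$manifest
  occ <- man$occurrences
  occ$entry <- unname(man$entry_of[occ$mature_id])
  hp_of <- stats::setNames(ref$hairpin$seq, ref$hairpin$id)
  o5_vals <- as.integer(names(params$offset5_probs))
  o3_vals <- as.integer(names(params$offset3_probs))
  n5 <- length(o5_vals); n3 <- length(o3_vals)
  # precompute every occurrence x offset-combination insert
  combo_insert <- matrix("", nrow = nrow(occ), ncol = n5 * n3)
  for (i in seq_len(nrow(occ))) {
    hseq <- hp_of[[occ$hairpin_id[i]]]
    for (a in seq_len(n5)) for (b in seq_len(n3)) {
      combo_insert[i, (a - 1L) * n3 + b] <-
        substr(hseq, occ$start[i] + o5_vals[a] + 1L, occ$end[i] + o3_vals[b])
    }
  }
  entries <- sort(unique(occ$entry))
  occ_by_entry <- split(seq_len(nrow(occ)), occ$entry)
  # expression profile shared across samples; trace entries are sporadic and
  # drawn from the ordinary arms so the planted structures stay well covered
  struct_matures <- c(unlist(man$structures[c("identical_matures",
                                              "overlap_cluster",
                                              "revcomp_pair")]),
                      "syn-miR-005-5p", "syn-miR-006-5p")
  struct_entries <- unique(unname(man$entry_of[
    intersect(struct_matures, names(man$entry_of))]))
  ordinary <- !(entries %in% struct_entries)
  n_trace <- ceiling(params$trace_fraction * sum(ordinary))
  trace_entries <- utils::tail(entries[ordinary], n_trace)
  core_entries <- setdiff(entries, trace_entries)
  core_w <- stats::rlnorm(length(core_entries), 0, params$abundance_sdlog)
  core_w <- core_w / sum(core_w)
  samples <- sprintf("S%02d", seq_len(params$n_samples))
  bases <- c("A", "C", "G", "T")
  out_reads <- out_ids <- stats::setNames(vector("list", params$n_samples), samples)
  truth_rows <- list()
  for (s in samples) {
    n_total <- params$reads_per_sample
    n_noise <- if (!is.null(genome)) round(params$noise_fraction * n_total) else 0L
    n_decoy <- if (!is.null(genome)) min(params$decoy_reads_per_sample,
                                         n_total - n_noise) else 0L
    trace_n <- if (length(trace_entries)) {
      stats::rpois(length(trace_entries), params$trace_mean) *
        stats::rbinom(length(trace_entries), 1L, params$trace_presence)
    } else integer(0)
    avail <- n_total - n_noise - n_decoy
    if (sum(trace_n) > avail) trace_n[cumsum(trace_n) > avail] <- 0L
    n_core <- avail - sum(trace_n)
    entry_vec <- c(rep(core_entries, stats::rmultinom(1, n_core, core_w)[, 1]),
                   rep(trace_entries, trace_n))
    n_mir <- length(entry_vec)
    occ_idx <- vapply(occ_by_entry[entry_vec], function(ix)
      if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
    a <- sample.int(n5, n_mir, replace = TRUE, prob = params$offset5_probs)
    b <- sample.int(n3, n_mir, replace = TRUE, prob = params$offset3_probs)
    inserts <- combo_insert[cbind(occ_idx, (a - 1L) * n3 + b)]
    noise_ins <- character(0); noise_id <- character(0)
    if (n_noise > 0L) {
      plain <- genome$contigs[startsWith(genome$contigs$id, "decoy_") &
                                genome$contigs$id != "decoy_variant", , drop = FALSE]
      ci <- sample.int(nrow(plain), n_noise, replace = TRUE)
      nl <- sample(18:26, n_noise, replace = TRUE)
      np <- vapply(seq_len(n_noise), function(k)
        sample.int(nchar(plain$seq[ci[k]]) - nl[k] + 1L, 1L), integer(1))
      noise_ins <- substr(plain$seq[ci], np, np + nl - 1L)
      flip <- stats::runif(n_noise) < 0.5
      noise_ins[flip] <- revcomp(noise_ins[flip])
      noise_id <- sprintf("noise|%s|%d|%s|%d", plain$id[ci], np,
                          ifelse(flip, "-", "+"), seq_len(n_noise))
    }
    decoy_ins <- rep(if (n_decoy > 0L) genome$variant$seq else character(0), n_decoy)
    all_ins <- c(inserts, noise_ins, decoy_ins)
    origin <- rep(c("mirna", "noise", "decoy"),
                  c(n_mir, length(noise_ins), length(decoy_ins)))
    # note: paste0(character(0), x) recycles to one element, hence the guard
    reads <- if (length(all_ins)) paste0(all_ins, params$adapter) else character(0)
    short <- nchar(reads) < params$read_length
    reads[short] <- paste0(reads[short],
                           strrep("A", params$read_length))
    reads <- substr(reads, 1L, params$read_length)
    # substitution errors on the sequenced read (insert and adapter alike);
    # planted decoy reads stay error-free so their genomic match is exact
    n_err <- stats::rbinom(length(reads), params$read_length, params$error_rate)
    n_err[origin == "decoy"] <- 0L
    n_err_insert <- integer(length(reads))
    ins_len <- nchar(all_ins)
    for (k in which(n_err > 0L)) {
      pos <- sample.int(params$read_length, n_err[k])
      for (p in pos) {
        old <- substr(reads[k], p, p)
        substr(reads[k], p, p) <- sample(setdiff(bases, old), 1L)
      }
      n_err_insert[k] <- sum(pos <= ins_len[k])
    }
    ids <- c(
      if (n_mir) sprintf("mir|%s|%d|%d|%s|%d|e%d", entry_vec, o5_vals[a],
                         o3_vals[b], s, seq_len(n_mir), n_err[seq_len(n_mir)]),
      noise_id,
      if (n_decoy) sprintf("decoy|%d", seq_len(n_decoy))
    )
    tr <- data.frame(
      sample = rep(s, length(origin)), origin = origin,
      entry_id = c(entry_vec, rep(NA_character_, length(noise_ins)),
                   rep(if (n_decoy > 0L) genome$variant$source_entry else
                         NA_character_, length(decoy_ins))),
      offset5 = c(o5_vals[a], rep(NA_integer_, length(all_ins) - n_mir)),
      offset3 = c(o3_vals[b], rep(NA_integer_, length(all_ins) - n_mir)),
      n_err = n_err, n_err_insert = n_err_insert,
      insert = substr(reads, 1L, ins_len),
      stringsAsFactors = FALSE
    )
    perm <- sample.int(length(reads))
    out_reads[[s]] <- reads[perm]
    out_ids[[s]] <- ids[perm]
    truth_rows[[s]] <- tr[perm, , drop = FALSE]
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(reads = out_reads, ids = out_ids, truth = truth)
}

#' Generate a complete synthetic experiment in memory
#'
#' Convenience wrapper: reference, genome, reads and truth in one call.
#'
#' @param params A `synth_params` object (default [synth_params()]).
#' @param with_genome Generate genome, noise and decoy reads (default `TRUE`).
#' @return List with `reference`, `genome` (or `NULL`), `reads`, `ids`,
#'   `truth` and `params`.
#' @export
synth_experiment <- function(params = synth_params(), with_genome = TRUE) {
  ref <- synth_reference(params)
  gen <- if (with_genome) synth_genome(ref, params) else NULL
  sim <- simulate_reads(ref, gen, params)
  list(reference = ref, genome = gen, reads = sim$reads, ids = sim$ids,
       truth = sim$truth, params = params)
}

#' Ground-truth miRNA and isomiR count matrices
#'
#' Aggregates the read-level truth into matrices directly comparable to the
#' pipeline's `standard` count tables. With an error rate of zero (and the
#' noise filter off) the pipeline must reproduce these exactly; with errors,
#' reads carrying an insert error leave their truth cell by construction.
#'
#' @param truth Truth table from [simulate_reads()].
#' @param samples Sample order (default: sorted unique samples of `truth`).
#' @param error_free_only Count only reads without insert errors
#'   (default `FALSE`).
#' @return List with `mirna` (entry x sample) and `isomir`
#'   (`entry|o5|o3` x sample) integer matrices.
#' @export
truth_counts <- function(truth, samples = NULL, error_free_only = FALSE) {
  tt <- truth[truth$origin == "mirna", , drop = FALSE]
  if (error_free_only) tt <- tt[tt$n_err_insert == 0L, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(truth$sample))
  mk <- function(key) {
    u <- sort(unique(key))
    m <- matrix(0L, nrow = length(u), ncol = length(samples),
                dimnames = list(u, samples))
    tab <- table(key, factor(tt$sample, levels = samples))
    m[rownames(tab), ] <- as.integer(tab)
    m
  }
  list(mirna = mk(tt$entry_id),
       isomir = mk(paste(tt$entry_id, tt$offset5, tt$offset3, sep = "|")))
}

#' Write a synthetic experiment to disk
#'
#' Emits `mature.fa` and `hairpin.fa` in the miRBase dialect (RNA alphabet),
#' `genome.fa`, one gzipped FASTQ per sample (dummy qualities: the pipeline
#' ignores base quality), `truth.tsv` and `manifest.json`. Byte-deterministic
#' for fixed parameters.
#'
#' @param dir Output directory.
#' @param params A `synth_params` object.
#' @return Invisibly, the in-memory experiment (see [synth_experiment()])
#'   with a `files` element appended.
#' @export
synth_dataset <- function(dir, params = synth_params()) {
  exp <- synth_experiment(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(mature = file.path(dir, "mature.fa"),
             hairpin = file.path(dir, "hairpin.fa"),
             genome = file.path(dir, "genome.fa"))
  write_fasta(exp$reference$mature$id, chartr("T", "U", exp$reference$mature$seq),
              files["mature"])
  write_fasta(exp$reference$hairpin$id, chartr("T", "U", exp$reference$hairpin$seq),
              files["hairpin"])
  write_fasta(exp$genome$contigs$id, exp$genome$contigs$seq, files["genome"])
  for (s in names(exp$reads)) {
    fq <- file.path(dir, paste0(s, ".fastq.gz"))
    con <- gzfile(fq, "w")
    writeLines(paste0("@", exp$ids[[s]], "\n", exp$reads[[s]], "\n+\n",
                      strrep("I", nchar(exp$reads[[s]]))), con)
    close(con)
    files[s] <- fq
  }
  files["truth"] <- file.path(dir, "truth.tsv")
  utils::write.table(exp$truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["manifest"] <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(occurrences = exp$reference$manifest$occurrences,
         entry_of = as.list(exp$reference$manifest$entry_of),
         structures = exp$reference$manifest$structures,
         variant = exp$genome$variant,
         params = unclass(params)),
    files["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  exp$files <- files
  invisible(exp)
}
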