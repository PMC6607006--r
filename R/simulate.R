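# tRNA isotypes used by the reference simulator: amino acid + anticodon pairs
# drawn from common mouse cytosolic tRNA species.
TRNA_ISOTYPES <- tibble::tibble(
  amino_acid = c("Gln", "Glu", "Gly", "Val", "Lys", "His", "Asp", "Ala",
                 "Cys", "Met", "Arg", "Leu", "Ser", "Pro", "Thr", "Phe",
                 "Tyr", "Trp", "Asn", "Ile"),
  anticodon  = c("CTG", "TTC", "GCC", "AAC", "CTT", "GTG", "GTC", "AGC",
                 "GCA", "CAT", "TCT", "CAA", "GCT", "TGG", "TGT", "GAA",
                 "GTA", "CCA", "GTT", "AAT"))

#' Simulate a clustered tRNA reference
#'
#' Generates mature tRNA gene sequences (72-90 nt) with an anticodon triplet
#' planted at position 34-36. Genes are organised into planted clusters:
#' members of a cluster share an identical first 50 nt and differ only in
#' their 3' tail, so 5'-prefix clustering can be exercised and checked
#' against the manifest. The planted anticodon occurrence is made unique
#' within the canonical search window so annotation-free anticodon location
#' is exact.
#'
#' @param n_genes Number of tRNA genes to emit.
#' @param n_anticodons Number of distinct anticodons (isotypes) to use.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `genes` (tibble as from [read_trna_reference()]),
#'   `manifest` (tibble `gene_id`, `cluster_key`, `anticodon`,
#'   `anticodon_start`) and `n_clusters` (planted cluster count).
#' @export
simulate_trna_reference <- function(n_genes = 60L, n_anticodons = 12L,
                                    seed = 1L) {
  if (n_anticodons < 1L || n_genes < n_anticodons) {
    stopf("need n_genes >= n_anticodons >= 1")
  }
  if (n_anticodons > nrow(TRNA_ISOTYPES)) {
    stopf("at most %d distinct anticodons supported", nrow(TRNA_ISOTYPES))
  }
  withr::with_seed(seed, {
    iso <- TRNA_ISOTYPES[seq_len(n_anticodons), ]
    n_clusters <- max(n_anticodons, ceiling(n_genes / 2))
    n_clusters <- min(n_clusters, n_genes)
    cluster_iso <- iso[rep_len(seq_len(n_anticodons), n_clusters), ]

    base_seqs <- character(n_clusters)
    ac_starts <- integer(n_clusters)
    for (k in seq_len(n_clusters)) {
      repeat {
        len <- sample(72:90, 1L)
        s <- random_dna(1L, len)
        a <- sample(34:36, 1L)
        substr(s, a, a + 2L) <- cluster_iso$anticodon[k]
        s <- scrub_triplet(s, cluster_iso$anticodon[k], keep = a,
                           window = c(30L, 40L))
        if (!is.null(s) &&
            !any(substr(s, 1L, 50L) == substr(base_seqs[seq_len(k - 1L)], 1L, 50L))) {
          base_seqs[k] <- s
          ac_starts[k] <- a
          break
        }
      }
    }

    # every cluster gets one gene; remaining genes are extra copies
    membership <- c(seq_len(n_clusters),
                    sample(n_clusters, n_genes - n_clusters, replace = TRUE))
    membership <- sort(membership)
    copy_no <- stats::ave(membership, membership, FUN = seq_along)

    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      s <- base_seqs[membership[i]]
      if (copy_no[i] > 1L) {
        # vary the 3' tail only, preserving the first-50-nt cluster key
        n_mut <- sample(1:3, 1L)
        pos <- sample(51:nchar(s), min(n_mut, nchar(s) - 50L))
        for (p in pos) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      seqs[i] <- s
    }

    genes <- tibble::tibble(
      gene_id = sprintf("tRNA-%s-%s-%d-%d",
                        cluster_iso$amino_acid[membership],
                        cluster_iso$anticodon[membership],
                        membership, copy_no),
      amino_acid = cluster_iso$amino_acid[membership],
      anticodon = cluster_iso$anticodon[membership],
      anticodon_start = ac_starts[membership],
      sequence = seqs)
    manifest <- tibble::tibble(
      gene_id = genes$gene_id,
      cluster_key = membership,
      anticodon = genes$anticodon,
      anticodon_start = genes$anticodon_start)
    list(genes = genes, manifest = manifest, n_clusters = n_clusters)
  })
}

# Remove stray occurrences of `triplet` starting in `window` (other than the
# planted one at `keep`) by point mutation outside the planted bases.
# Returns NULL if a clean sequence cannot be produced in a few rounds.
scrub_triplet <- function(s, triplet, keep, window) {
  for (round in 1:20) {
    starts <- window[1]:min(window[2], nchar(s) - 2L)
    hits <- starts[substring(s, starts, starts + 2L) == triplet]
    hits <- setdiff(hits, keep)
    if (length(hits) == 0L) return(s)
    p <- hits[1]
    editable <- setdiff(p:(p + 2L), keep:(keep + 2L))
    if (length(editable) == 0L) return(NULL)
    q <- editable[1]
    cur <- substr(s, q, q)
    substr(s, q, q) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  NULL
}

#' Write a simulated tRNA reference to FASTA + annotation TSV
#'
#' @param ref List from [simulate_trna_reference()] (or any tibble with the
#'   gene columns under `$genes`).
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_trna_reference <- function(ref, fasta_path, annotation_path) {
  genes <- if (is.data.frame(ref)) ref else ref$genes
  write_trna_fasta(genes, fasta_path)
  readr::write_tsv(
    genes %>% dplyr::select("gene_id", "amino_acid", "anticodon",
                            "anticodon_start"),
    annotation_path)
  invisible(list(fasta = fasta_path, annotation = annotation_path))
}

#' Simulate background contigs (genome decoys or rRNA)
#'
#' @param n_contigs Number of contigs.
#' @param length Length of each contig (nt).
#' @param prefix Contig id prefix.
#' @param seed Integer seed.
#' @return Tibble with `contig_id`, `sequence`.
#' @export
simulate_contigs <- function(n_contigs = 3L, length = 1000L,
                             prefix = "decoy", seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      contig_id = sprintf("%s_%d", prefix, seq_len(n_contigs)),
      sequence = random_dna(n_contigs, length))
  })
}

#' Build a small-RNA library simulation configuration
#'
#' Component fractions are over all emitted reads; the remainder
#' (`1 - tsrna_fraction - mirna_fraction - rrna_fraction`) is a genomic decoy
#' background. By default that background is 30-35 nt, emulating the
#' non-tRNA component of the 30-35 nt read population that the tRNA-fraction
#' statistic is computed against, so `tsrna_fraction` is (in expectation) the
#' tRNA fraction among 30-35 nt genome-mapped reads.
#'
#' @param n_reads Number of reads to emit.
#' @param tsrna_fraction,mirna_fraction,rrna_fraction Class fractions; must
#'   sum to at most 1.
#' @param producing_cluster_weights Optional named probability vector
#'   (cluster_id -> weight) for the tsRNA-producing clusters; by default the
#'   five first clusters produce with linearly decreasing weights, mirroring
#'   the observation that only a small subset of tRNAs is processed.
#' @param adapter 3' adapter appended to every insert.
#' @param error_rate Per-base substitution probability.
#' @param read_length Fixed machine read length after adapter addition.
#' @param genomic_length_range Length range of genomic background reads.
#' @param seed Integer seed.
#' @return A `library_config` list.
#' @export
library_config <- function(n_reads = 10000L, tsrna_fraction = 0.5,
                           mirna_fraction = 0.25, rrna_fraction = 0.15,
                           producing_cluster_weights = NULL,
                           adapter = TSRNA_ADAPTER, error_rate = 0.001,
                           read_length = 50L,
                           genomic_length_range = c(30L, 35L), seed = 1L) {
  fr <- c(tsrna_fraction, mirna_fraction, rrna_fraction)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stopf("class fractions must be nonnegative and sum to at most 1")
  }
  structure(list(
    n_reads = as.integer(n_reads), tsrna_fraction = tsrna_fraction,
    mirna_fraction = mirna_fraction, rrna_fraction = rrna_fraction,
    producing_cluster_weights = producing_cluster_weights,
    adapter = adapter, error_rate = error_rate,
    read_length = as.integer(read_length),
    genomic_length_range = as.integer(genomic_length_range),
    seed = as.integer(seed)), class = "library_config")
}

#' Simulate a small-RNA sequencing library with ground truth
#'
#' Emits reads of four classes. 5'-tsRNA reads start at nucleotide 1-4 of a
#' producing cluster's representative and end 1-3 nt before the anticodon
#' (final length clipped to 30-35 nt; impossible geometries are re-drawn).
#' miRNA-like reads are 21-23 nt decoy substrings, rRNA reads 28-35 nt rRNA
#' substrings, and the remainder genomic decoy substrings. Every insert gets
#' the 3' adapter appended and is truncated to the machine read length;
#' per-base substitution errors are applied at `error_rate`; qualities are a
#' constant "I".
#'
#' @param config A [library_config()].
#' @param clusters Cluster tibble from [cluster_trnas()].
#' @param decoys,rrna Contig tibbles (`contig_id`, `sequence`); may be NULL
#'   when the corresponding class fraction is zero.
#' @return List with `reads` (tibble `read_id`, `sequence`, `quality`),
#'   `manifest` (per-read truth: class, source, coordinates, strand, insert)
#'   and `config`.
#' @export
simulate_small_rna_library <- function(config, clusters, decoys = NULL,
                                       rrna = NULL) {
  stopifnot(inherits(config, "library_config"))
  n <- config$n_reads
  if (n == 0L) {
    empty <- tibble::tibble(read_id = character(), sequence = character(),
                            quality = character())
    manifest <- tibble::tibble(read_id = character(), class = character(),
                               source_id = character(), start = integer(),
                               end = integer(), strand = character(),
                               insert_length = integer(), insert = character())
    return(list(reads = empty, manifest = manifest, config = config))
  }
  p_genomic <- 1 - config$tsrna_fraction - config$mirna_fraction -
    config$rrna_fraction
  if ((config$mirna_fraction > 0 || p_genomic > 1e-12) && is.null(decoys)) {
    stopf("decoy contigs required for miRNA/genomic read classes")
  }
  if (config$rrna_fraction > 0 && is.null(rrna)) {
    stopf("rRNA reference required for rRNA read class")
  }

  weights <- config$producing_cluster_weights
  if (is.null(weights)) {
    k <- min(5L, nrow(clusters))
    weights <- stats::setNames(rev(seq_len(k)) / sum(seq_len(k)),
                               clusters$cluster_id[seq_len(k)])
  }
  if (abs(sum(weights) - 1) > 1e-8) stopf("cluster weights must sum to 1")
  if (!all(names(weights) %in% clusters$cluster_id)) {
    stopf("producing_cluster_weights names unknown cluster ids")
  }

  withr::with_seed(config$seed, {
    class <- sample(c("tsrna", "mirna", "rrna", "genomic"), n, replace = TRUE,
                    prob = c(config$tsrna_fraction, config$mirna_fraction,
                             config$rrna_fraction, max(p_genomic, 0)))
    source_id <- character(n)
    start <- integer(n)
    end <- integer(n)
    strand <- rep("+", n)
    insert <- character(n)

    cl_lookup <- clusters[match(names(weights), clusters$cluster_id), ]
    is_ts <- class == "tsrna"
    n_ts <- sum(is_ts)
    if (n_ts > 0L) {
      pick <- sample(length(weights), n_ts, replace = TRUE, prob = weights)
      ac <- cl_lookup$anticodon_start[pick]
      s <- integer(n_ts); e <- integer(n_ts)
      for (i in seq_len(n_ts)) {
        ok <- FALSE
        for (try in 1:100) {
          si <- sample(1:4, 1L)
          ei <- sample((ac[i] - 3L):(ac[i] - 1L), 1L)
          if (ei - si + 1L > 35L) ei <- si + 34L
          if (ei - si + 1L >= 30L) { ok <- TRUE; break }
        }
        if (!ok) stopf("tsRNA read geometry impossible for cluster %s",
                       cl_lookup$cluster_id[pick[i]])
        s[i] <- si; e[i] <- ei
      }
      source_id[is_ts] <- cl_lookup$cluster_id[pick]
      start[is_ts] <- s
      end[is_ts] <- e
      insert[is_ts] <- substr(cl_lookup$representative_sequence[pick], s, e)
    }

    draw_background <- function(idx, contigs, len_lo, len_hi) {
      m <- length(idx)
      if (m == 0L) return(invisible(NULL))
      ci <- sample(nrow(contigs), m, replace = TRUE)
      len <- sample(len_lo:len_hi, m, replace = TRUE)
      clen <- nchar(contigs$sequence[ci])
      if (any(len > clen)) stopf("contig shorter than requested read length")
      st <- floor(stats::runif(m, 1, clen - len + 1 + 1))
      st <- pmin(st, clen - len + 1)
      en <- st + len - 1L
      fwd <- substr(contigs$sequence[ci], st, en)
      neg <- stats::runif(m) < 0.5
      seqs <- fwd
      seqs[neg] <- revcomp(fwd[neg])
      source_id[idx] <<- contigs$contig_id[ci]
      start[idx] <<- as.integer(st)
      end[idx] <<- as.integer(en)
      strand[idx] <<- ifelse(neg, "-", "+")
      insert[idx] <<- seqs
      invisible(NULL)
    }
    draw_background(which(class == "mirna"), decoys, 21L, 23L)
    draw_background(which(class == "rrna"), rrna, 28L, 35L)
    draw_background(which(class == "genomic"), decoys,
                    config$genomic_length_range[1],
                    config$genomic_length_range[2])

    raw <- substr(paste0(insert, config$adapter), 1L, config$read_length)
    if (config$error_rate > 0) {
      raw <- vapply(raw, function(x) {
        ch <- strsplit(x, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < config$error_rate)
        for (p in hit) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }

    read_id <- sprintf("read_%06d", seq_len(n))
    reads <- tibble::tibble(read_id = read_id, sequence = raw,
                            quality = strrep("I", nchar(raw)))
    manifest <- tibble::tibble(read_id = read_id, class = class,
                               source_id = source_id, start = start,
                               end = end, strand = strand,
                               insert_length = nchar(insert), insert = insert)
    list(reads = reads, manifest = manifest, config = config)
  })
}

#' Simulate a 4-sample pulldown count matrix with planted enrichment
#'
#' Counts for samples LIF_scr, LIF_ts, RA_scr and RA_ts are drawn
#' negative-binomial (variance = mean + dispersion * mean^2) around a
#' lognormal per-transcript baseline. Planted transcripts carry a `true_fc`
#' multiplier in the ts sample of their planted condition(s): state
#' `RA_enriched` in RA_ts, `LIF_enriched` in LIF_ts, `ubiquitous` in both.
#'
#' @param n_transcripts,n_enriched Numbers of transcripts and planted
#'   enriched transcripts.
#' @param true_fc Planted fold change (> 1).
#' @param baseline_mean Mean baseline count (lognormal across transcripts,
#'   sdlog 0.5, mean preserved).
#' @param dispersion NB dispersion; 0 gives Poisson counts.
#' @param depth_factors Named multipliers for the four samples.
#' @param state_probs Probabilities of the three planted states.
#' @param seed Integer seed.
#' @return List with `counts` (tibble `transcript_id` + 4 sample columns)
#'   and `manifest` (tibble `transcript_id`, `state` for planted rows).
#' @export
simulate_pulldown_counts <- function(n_transcripts = 5000L, n_enriched = 100L,
                                     true_fc = 4, baseline_mean = 200,
                                     dispersion = 0.1,
                                     depth_factors = c(LIF_scr = 1, LIF_ts = 1,
                                                       RA_scr = 1, RA_ts = 1),
                                     state_probs = c(RA_enriched = 0.5,
                                                     LIF_enriched = 0.25,
                                                     ubiquitous = 0.25),
                                     seed = 1L) {
  if (true_fc <= 1) stopf("true_fc must be > 1")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  samples <- c("LIF_scr", "LIF_ts", "RA_scr", "RA_ts")
  if (!all(samples %in% names(depth_factors))) {
    stopf("depth_factors must name all of %s", paste(samples, collapse = ", "))
  }
  withr::with_seed(seed, {
    sdlog <- 0.5
    lambda <- stats::rlnorm(n_transcripts,
                            meanlog = log(baseline_mean) - sdlog^2 / 2,
                            sdlog = sdlog)
    planted <- sort(sample(n_transcripts, n_enriched))
    states <- sample(names(state_probs), n_enriched, replace = TRUE,
                     prob = state_probs)
    fc_lif <- rep(1, n_transcripts)
    fc_ra <- rep(1, n_transcripts)
    fc_lif[planted[states != "RA_enriched"]] <- true_fc
    fc_ra[planted[states != "LIF_enriched"]] <- true_fc

    mu <- cbind(LIF_scr = lambda * depth_factors[["LIF_scr"]],
                LIF_ts = lambda * fc_lif * depth_factors[["LIF_ts"]],
                RA_scr = lambda * depth_factors[["RA_scr"]],
                RA_ts = lambda * fc_ra * depth_factors[["RA_ts"]])
    draw <- function(m) {
      if (dispersion > 0) stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
      else stats::rpois(length(m), m)
    }
    counts <- apply(mu, 2, draw)
    ids <- sprintf("tx_%05d", seq_len(n_transcripts))
    list(
      counts = tibble::as_tibble(counts) %>%
        dplyr::mutate(transcript_id = ids, .before = 1),
      manifest = tibble::tibble(transcript_id = ids[planted], state = states))
  })
}

#' Simulate a generic two-group NB count matrix
#'
#' Counts with variance = mean + dispersion * mean^2 around a lognormal
#' per-feature baseline (sdlog 0.5, mean preserved), optionally with `n_de`
#' planted features carrying `true_fc` in group B and per-sample depth
#' factors. Used for normalization and differential-test calibration
#' studies.
#'
#' @param n_features Number of features.
#' @param group_sizes Integer vector of length 2: samples per group (use
#'   `c(n, 0)` for a single-group design).
#' @param baseline_mean Mean baseline count.
#' @param dispersion NB dispersion; 0 gives Poisson.
#' @param true_fc Planted fold change for the `n_de` features (group B).
#' @param n_de Number of planted differential features.
#' @param depth_factors Optional per-sample depth multipliers.
#' @param seed Integer seed.
#' @return List with `counts` (tibble, samples `A1..`, `B1..`), `groups`
#'   (named vector) and `manifest` (planted feature ids).
#' @export
simulate_nb_counts <- function(n_features = 2000L, group_sizes = c(2L, 2L),
                               baseline_mean = 100, dispersion = 0.1,
                               true_fc = 1, n_de = 0L, depth_factors = NULL,
                               seed = 1L) {
  n_samples <- sum(group_sizes)
  samples <- c(sprintf("A%d", seq_len(group_sizes[1])),
               if (group_sizes[2] > 0) sprintf("B%d", seq_len(group_sizes[2])))
  groups <- stats::setNames(rep(c("A", "B"), group_sizes), samples)
  if (is.null(depth_factors)) depth_factors <- rep(1, n_samples)
  withr::with_seed(seed, {
    sdlog <- 0.5
    lambda <- stats::rlnorm(n_features,
                            meanlog = log(baseline_mean) - sdlog^2 / 2,
                            sdlog = sdlog)
    de_idx <- if (n_de > 0) sort(sample(n_features, n_de)) else integer(0)
    fc <- rep(1, n_features)
    fc[de_idx] <- true_fc
    m <- matrix(0L, n_features, n_samples, dimnames = list(NULL, samples))
    for (j in seq_len(n_samples)) {
      mu <- lambda * depth_factors[j] * (if (groups[j] == "B") fc else 1)
      m[, j] <- if (dispersion > 0) {
        stats::rnbinom(n_features, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(n_features, mu)
      }
    }
    ids <- sprintf("f_%05d", seq_len(n_features))
    list(counts = tibble::as_tibble(m) %>%
           dplyr::mutate(feature_id = ids, .before = 1),
         groups = groups,
         manifest = tibble::tibble(feature_id = ids[de_idx]))
  })
}

#' Simulate a reference RA-response fold-change table
#'
#' Emulates a public RA-treatment transcriptome: a fraction of transcripts
#' is >2-fold upregulated (differentiation-responsive), a fraction >2-fold
#' downregulated (pluripotency-associated), and the rest lies strictly
#' between 0.5- and 2-fold.
#'
#' @param transcript_ids Character vector of transcript ids.
#' @param frac_up,frac_down Fractions of up-/down-regulated transcripts.
#' @param seed Integer seed.
#' @return List with `table` (tibble `transcript_id`, `reference_fc`) and
#'   `manifest` (tibble `transcript_id`, `class`).
#' @export
simulate_reference_fc_table <- function(transcript_ids, frac_up = 0.2,
                                        frac_down = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    n <- length(transcript_ids)
    class <- sample(c("differentiation_responsive", "pluripotency_associated",
                      "other"), n, replace = TRUE,
                    prob = c(frac_up, frac_down, 1 - frac_up - frac_down))
    fc <- 2^stats::runif(n, -0.9, 0.9)
    fc[class == "differentiation_responsive"] <-
      2^stats::runif(sum(class == "differentiation_responsive"), 1.2, 3)
    fc[class == "pluripotency_associated"] <-
      2^-stats::runif(sum(class == "pluripotency_associated"), 1.2, 3)
    list(table = tibble::tibble(transcript_id = transcript_ids,
                                reference_fc = fc),
         manifest = tibble::tibble(transcript_id = transcript_ids,
                                   class = class))
  })
}

#' Simulate an emPAI table with non-detects and planted enrichment
#'
#' Emits bead-control, LIF and RA emPAI columns. Planted proteins carry a
#' `fold`-times larger (RA-enriched) or smaller (LIF-enriched)
#' bead-subtracted abundance in RA vs LIF; bead-dominant rows have a bead
#' signal exceeding both conditions; non-detects are marked with the -1
#' sentinel. One background row's bead value is pinned at 0.01 so the
#' table's lowest detected value is stable.
#'
#' @param n_proteins,n_enriched Numbers of proteins and planted enriched
#'   proteins (split between RA and LIF).
#' @param seed Integer seed.
#' @param cv Multiplicative (lognormal) noise CV; 0 for exact tables.
#' @param fold Planted adjusted-abundance fold change.
#' @param nondetect_rate Fraction of background rows whose bead value is the
#'   -1 sentinel.
#' @param n_bead_dominant Number of planted bead-dominant rows.
#' @return List with `table` (tibble `protein_id`, `beads`, `LIF`, `RA`) and
#'   `manifest` (`protein_id`, `enriched` in RA/LIF/none, `bead_dominant`).
#' @export
simulate_empai_table <- function(n_proteins = 500L, n_enriched = 20L,
                                 seed = 1L, cv = 0, fold = 4,
                                 nondetect_rate = 0.15,
                                 n_bead_dominant = 10L) {
  if (n_enriched + n_bead_dominant > n_proteins) {
    stopf("planted rows exceed n_proteins")
  }
  withr::with_seed(seed, {
    ids <- sprintf("prot_%04d", seq_len(n_proteins))
    a <- stats::runif(n_proteins, 0.05, 2)
    beads <- stats::runif(n_proteins, 0.02, 0.08)
    planted <- sample(n_proteins, n_enriched + n_bead_dominant)
    enr <- planted[seq_len(n_enriched)]
    dom <- setdiff(planted, enr)
    enr_state <- rep(c("RA", "LIF"), length.out = n_enriched)

    f <- rep(1, n_proteins)
    f[enr[enr_state == "RA"]] <- fold
    f[enr[enr_state == "LIF"]] <- 1 / fold
    LIF <- beads + a
    RA <- beads + a * f
    beads[dom] <- stats::runif(length(dom), 0.5, 1)
    LIF[dom] <- beads[dom] * stats::runif(length(dom), 0.2, 0.8)
    RA[dom] <- beads[dom] * stats::runif(length(dom), 0.2, 0.8)

    background <- setdiff(seq_len(n_proteins), planted)
    beads[background[1]] <- 0.01
    if (cv > 0) {
      s <- sqrt(log(1 + cv^2))
      noise <- function(x) x * exp(stats::rnorm(length(x), -s^2 / 2, s))
      beads <- noise(beads); LIF <- noise(LIF); RA <- noise(RA)
    }
    nd <- background[-1][stats::runif(length(background) - 1) < nondetect_rate]
    beads[nd] <- -1

    enriched <- rep("none", n_proteins)
    enriched[enr] <- enr_state
    list(
      table = tibble::tibble(protein_id = ids, beads = beads, LIF = LIF,
                             RA = RA),
      manifest = tibble::tibble(protein_id = ids, enriched = enriched,
                                bead_dominant = seq_len(n_proteins) %in% dom))
  })
}

#' Simulate equilibrium binding series
#'
#' Signal follows the one-site model `bmax * C / (kd + C)` with mean-one
#' lognormal multiplicative noise, then is normalized to the
#' highest-concentration point of its replicate (the band-intensity
#' normalization used for gel-shift quantitation).
#'
#' @param kd_nM True dissociation constant (nM).
#' @param bmax True saturation asymptote.
#' @param concentrations_nM Protein concentration series (nM).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Number of independent series.
#' @param seed Integer seed.
#' @return Tibble with `replicate`, `conc_nM`, `signal`, `normalized`.
#' @export
simulate_binding_series <- function(kd_nM = 33, bmax = 1,
                                    concentrations_nM = c(20, 40, 80, 200, 400),
                                    cv = 0.02, n_replicates = 1L, seed = 1L) {
  if (kd_nM <= 0) stopf("kd_nM must be > 0")
  if (cv < 0) stopf("cv must be >= 0")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      mu <- bmax * concentrations_nM / (kd_nM + concentrations_nM)
      if (cv > 0) {
        s <- sqrt(log(1 + cv^2))
        mu <- mu * exp(stats::rnorm(length(mu), -s^2 / 2, s))
      }
      tibble::tibble(replicate = r, conc_nM = concentrations_nM, signal = mu,
                     normalized = mu / mu[which.max(concentrations_nM)])
    })
  })
}
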