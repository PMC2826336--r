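QTL_TRAITS <- c("COLDTL", "SDLVIG", "OSADJCAP", "SALTSN", "CHLCN",
                "LFRL", "GERMSP")

TF_FAMILIES <- c("bZIP", "AP2/ERF", "MYB", "WRKY", "bHLH", "NAC")

#' Configuration of the synthetic study generator
#'
#' The defaults reproduce the design of the emulated study: ten chilling
#' sampling hours and three oxidative-mimic hours, two biological
#' replicates, an upregulated transcriptome split 71/22/7 percent across
#' phases 1/2/3, 18 co-expression clusters (12 phase-1, 5 phase-2, 1
#' phase-3), 1,200-nt promoter windows, and a cis-element planted per
#' cluster at 70 percent occurrence.
#'
#' @param n_genes number of genes in the universe (default 2000).
#' @param tf_fraction fraction of genes that are transcription factors
#'   (default 0.06).
#' @param chilling_timepoints,h2o2_timepoints sampling hours.
#' @param phase_mixture proportions of upregulated non-TF genes induced at
#'   phases 1/2/3; must sum to 1.
#' @param n_clusters number of co-expression clusters (default 18).
#' @param up_fraction,down_fraction fractions of the universe up- and
#'   downregulated by chilling (defaults 0.30 and 0.30, mirroring the
#'   2,604 : 6,064 split of an 8,668-gene responsive set).
#' @param per_cluster_h2o2_fraction named proportions of cluster members
#'   also responsive to the oxidative mimic, per cluster phase.
#' @param planted_motifs optional data.frame (`pattern`, `cluster`, `rate`,
#'   `class`) overriding the default one-element-class-per-cluster
#'   planting.
#' @param planted_rate default per-cluster planting rate (default 0.7).
#' @param promoter_length promoter window length in nt (default 1200).
#' @param background_order Markov order of the promoter background (0 =
#'   i.i.d. draws from `base_comp`).
#' @param base_comp background base composition (A, C, G, T).
#' @param noise_sd per-replicate Gaussian noise on log2 ratios (default
#'   0.25).
#' @param amplitude noise-free induced log2 ratio (default 3).
#' @param n_replicates biological replicates per cell (default 2).
#' @param n_qtl,qtl_width,qtl_enrichment_factor QTL map shape: number of
#'   intervals (default 46), width in bp, and the factor by which the
#'   QTL-association rate of upregulated TFs exceeds genome coverage.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param seed integer seed; every simulated quantity is a deterministic
#'   function of it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, tf_fraction = 0.06,
                              chilling_timepoints = c(0.5, 2, 4, 6, 12, 18,
                                                      24, 36, 48, 96),
                              h2o2_timepoints = c(1, 3, 6),
                              phase_mixture = c(0.71, 0.22, 0.07),
                              n_clusters = 18L,
                              up_fraction = 0.30, down_fraction = 0.30,
                              per_cluster_h2o2_fraction = c(`1` = 0.65,
                                                            `2` = 0.30,
                                                            `3` = 0.15),
                              planted_motifs = NULL, planted_rate = 0.7,
                              promoter_length = 1200L, background_order = 0L,
                              base_comp = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                              noise_sd = 0.25, amplitude = 3,
                              n_replicates = 2L,
                              n_qtl = 46L, qtl_width = 5e5,
                              qtl_enrichment_factor = 5,
                              chrom_lengths = stats::setNames(rep(3e7, 5),
                                                              paste0("chr", 1:5)),
                              seed = 1L) {
  if (abs(sum(phase_mixture) - 1) > 1e-9) stop("phase_mixture must sum to 1")
  if (any(phase_mixture < 0)) stop("phase_mixture must be non-negative")
  if (any(diff(chilling_timepoints) <= 0) || any(diff(h2o2_timepoints) <= 0)) {
    stop("time points must be strictly increasing")
  }
  if (planted_rate < 0 || planted_rate > 1) stop("occurrence rates must lie in [0, 1]")
  if (!is.null(planted_motifs) &&
      any(planted_motifs$rate < 0 | planted_motifs$rate > 1)) {
    stop("occurrence rates must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (up_fraction + down_fraction > 1) stop("up + down fractions exceed 1")
  if (is.null(names(chrom_lengths)) ||
      anyDuplicated(names(chrom_lengths)) > 0) {
    stop("chromosome names must be unique")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# sample() treats a length-1 numeric as 1:n; this always samples elements
sample_one <- function(v) v[sample.int(length(v), 1L)]

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the annotated gene universe
#'
#' @param config a [simulation_config()].
#' @return data.frame: `gene_id`, `is_tf`, `tf_family` (NA for non-TFs),
#'   `chrom`, `strand`, `tss`, `start`, `end` (1-based inclusive).
#' @export
generate_gene_universe <- function(config) {
  if (config$n_genes <= 0) stop("n_genes must be positive")
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))
    is_tf <- stats::runif(n) < config$tf_fraction
    tf_family <- ifelse(is_tf, sample(TF_FAMILIES, n, replace = TRUE),
                        NA_character_)
    chrom <- sample(names(config$chrom_lengths), n, replace = TRUE,
                    prob = config$chrom_lengths / sum(config$chrom_lengths))
    gene_len <- sample(1000:5000, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      L <- config$chrom_lengths[[chrom[i]]]
      sample.int(max(L - gene_len[i], 1L), 1L)
    }, numeric(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    end <- start + gene_len - 1L
    tss <- ifelse(strand == "+", start, end)
    data.frame(gene_id = gene_id, is_tf = is_tf, tf_family = tf_family,
               chrom = chrom, strand = strand, tss = tss,
               start = start, end = end, stringsAsFactors = FALSE)
  })
}

# Allocate clusters to phases: the observed 12/5/1 split when k = 18,
# otherwise largest-remainder apportionment of the phase mixture.
allocate_cluster_phases <- function(k, mixture) {
  if (k == 18L) return(rep(1:3, times = c(12L, 5L, 1L)))
  raw <- k * mixture
  base <- floor(raw)
  rem <- k - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  base <- pmax(base, ifelse(mixture > 0, 1, 0))
  while (sum(base) > k) {
    i <- which.max(base)
    base[i] <- base[i] - 1
  }
  rep(1:3, times = base)
}

# Distinct on/off induction templates per cluster, honouring phases:
# phase-1 onsets within 6 h, phase-2 within (6, 24], phase-3 after 24 h,
# every template spanning at least two consecutive samples.
cluster_templates <- function(phases, timepoints) {
  n_tp <- length(timepoints)
  onset_pool <- list(`1` = which(timepoints <= 6),
                     `2` = which(timepoints > 6 & timepoints <= 24),
                     `3` = which(timepoints > 24 & timepoints < max(timepoints)))
  templates <- matrix(0L, length(phases), n_tp)
  used <- character(0)
  for (i in seq_along(phases)) {
    pool <- onset_pool[[as.character(phases[i])]]
    repeat {
      onset <- sample_one(pool)
      len <- sample_one(2:min(6L, n_tp - onset + 1L))
      key <- paste(onset, len)
      if (!key %in% used || length(used) >= 40L) break
    }
    used <- c(used, key)
    templates[i, onset:(onset + len - 1L)] <- 1L
  }
  templates
}

#' Simulate the chilling and oxidative-mimic time courses
#'
#' Assigns every gene a ground-truth role (upregulated and clustered,
#' downregulated, or unresponsive; TFs get families and phases), builds
#' noise-free profiles from per-cluster induction templates, adds
#' per-replicate Gaussian noise, and derives per-cell p-values from a
#' two-sided one-sample t-test on the replicate log ratios.
#'
#' @param universe a [generate_gene_universe()] table.
#' @param config a [simulation_config()].
#' @return list with `chilling` and `h2o2` [time_course_matrix()] objects
#'   and `truth` (a `ground_truth` list: per-gene `genes` table, per-cluster
#'   `clusters` table, and the up/down/H2O2 id sets).
#' @export
simulate_timecourse <- function(universe, config) {
  if (nrow(universe) == 0L) stop("universe is empty")
  with_seed(config$seed + 1L, {
    catalog <- load_element_catalog()
    n <- nrow(universe)
    n_tp <- length(config$chilling_timepoints)
    k <- config$n_clusters
    cluster_phase <- allocate_cluster_phases(k, config$phase_mixture)
    templates <- cluster_templates(cluster_phase, config$chilling_timepoints)
    cluster_id <- cluster_labels(k)
    # planted regulator class per cluster, cycling through the catalog
    reg_class <- catalog$class[(seq_len(k) - 1L) %% nrow(catalog) + 1L]
    reg_broad <- catalog$broad_category[match(reg_class, catalog$class)]
    reg_family <- catalog$tf_family[match(reg_class, catalog$class)]

    role <- sample(c("up", "down", "null"), n, replace = TRUE,
                   prob = c(config$up_fraction, config$down_fraction,
                            1 - config$up_fraction - config$down_fraction))
    is_tf <- universe$is_tf
    gene_phase <- rep(NA_integer_, n)
    gene_cluster <- rep(NA_character_, n)

    up_ntf <- which(role == "up" & !is_tf)
    ph <- sample(1:3, length(up_ntf), replace = TRUE,
                 prob = config$phase_mixture)
    gene_phase[up_ntf] <- ph
    for (p in 1:3) {
      members <- up_ntf[ph == p]
      pool <- which(cluster_phase == p)
      if (length(pool) == 0L) pool <- seq_len(k)
      gene_cluster[members] <- cluster_id[pool[
        sample.int(length(pool), length(members), replace = TRUE)]]
    }

    # upregulated TFs: family-specific phases; guarantee one phase-1 up TF
    # per family so planted regulators always precede their clusters
    up_tf <- which(role == "up" & is_tf)
    gene_phase[up_tf] <- sample(1:3, length(up_tf), replace = TRUE,
                                prob = config$phase_mixture)
    for (fam in unique(reg_family)) {
      fam_tfs <- which(is_tf & universe$tf_family == fam)
      if (length(fam_tfs) == 0L) next
      has_p1 <- any(role[fam_tfs] == "up" & gene_phase[fam_tfs] == 1L,
                    na.rm = TRUE)
      if (!has_p1) {
        pick <- fam_tfs[1L]
        role[pick] <- "up"
        gene_phase[pick] <- 1L
        gene_cluster[pick] <- NA_character_
      }
    }

    # noise-free profiles
    mu <- matrix(0, n, n_tp)
    cl_idx <- match(gene_cluster, cluster_id)
    has_cl <- !is.na(cl_idx)
    mu[has_cl, ] <- templates[cl_idx[has_cl], , drop = FALSE] * config$amplitude
    tf_up <- which(role == "up" & is_tf)
    for (i in tf_up) {
      pool <- switch(gene_phase[i],
                     which(config$chilling_timepoints <= 6),
                     which(config$chilling_timepoints > 6 &
                             config$chilling_timepoints <= 24),
                     which(config$chilling_timepoints > 24 &
                             config$chilling_timepoints < max(config$chilling_timepoints)))
      onset <- sample_one(pool)
      len <- sample_one(2:min(4L, n_tp - onset + 1L))
      mu[i, onset:(onset + len - 1L)] <- config$amplitude
    }
    down <- which(role == "down")
    for (i in down) {
      n_rep_tp <- sample(1:3, 1L)
      at <- sample.int(n_tp, n_rep_tp)
      mu[i, at] <- -config$amplitude
    }

    chill <- noisy_matrix(mu, config, universe$gene_id,
                          config$chilling_timepoints)

    # oxidative-mimic responsiveness truth
    h2o2_resp <- rep(FALSE, n)
    frac_by_phase <- config$per_cluster_h2o2_fraction
    for (j in seq_len(k)) {
      members <- which(gene_cluster == cluster_id[j])
      f <- frac_by_phase[[as.character(cluster_phase[j])]]
      h2o2_resp[members] <- stats::runif(length(members)) < f
    }
    tf_h2o2_prob <- c(`1` = 0.5, `2` = 0.35, `3` = 0.2)
    for (i in tf_up) {
      h2o2_resp[i] <- stats::runif(1) < tf_h2o2_prob[[as.character(gene_phase[i])]]
    }
    mu_h <- matrix(0, n, length(config$h2o2_timepoints))
    for (i in which(h2o2_resp)) {
      at <- which(stats::runif(length(config$h2o2_timepoints)) < 0.7)
      if (length(at) == 0L) at <- sample.int(length(config$h2o2_timepoints), 1L)
      mu_h[i, at] <- config$amplitude
    }
    h2o2 <- noisy_matrix(mu_h, config, universe$gene_id,
                         config$h2o2_timepoints)

    clusters_tab <- data.frame(
      cluster = cluster_id, phase = cluster_phase,
      regulator_class = reg_class, regulator_broad = reg_broad,
      regulator_family = reg_family,
      pattern = catalog$iupac_pattern[match(reg_class, catalog$class)],
      h2o2_fraction = unname(vapply(seq_len(k), function(j) {
        members <- which(gene_cluster == cluster_id[j])
        if (length(members) == 0L) return(0)
        mean(h2o2_resp[members])
      }, numeric(1))),
      size = as.integer(table(factor(gene_cluster, levels = cluster_id))),
      stringsAsFactors = FALSE)

    genes_tab <- data.frame(
      gene_id = universe$gene_id, role = role, is_tf = is_tf,
      tf_family = universe$tf_family, phase = gene_phase,
      cluster = gene_cluster, h2o2 = h2o2_resp, stringsAsFactors = FALSE)

    truth <- structure(list(
      genes = genes_tab, clusters = clusters_tab,
      up = universe$gene_id[role == "up"],
      down = universe$gene_id[role == "down"],
      h2o2 = universe$gene_id[h2o2_resp]), class = "ground_truth")
    list(chilling = chill, h2o2 = h2o2, truth = truth)
  })
}

# Replicate-average ratios plus two-sided one-sample t-test p-values,
# vectorised over all cells. With zero replicate variance the p-value is 0
# for a non-zero mean and 1 otherwise.
noisy_matrix <- function(mu, config, gene_ids, timepoints) {
  n <- nrow(mu)
  n_tp <- ncol(mu)
  reps <- array(mu, dim = c(n, n_tp, config$n_replicates)) +
    stats::rnorm(n * n_tp * config$n_replicates, sd = config$noise_sd)
  mean_r <- rowMeans(reps, dims = 2L)
  sd_r <- sqrt(rowSums((reps - as.vector(mean_r))^2, dims = 2L) /
                 max(config$n_replicates - 1L, 1L))
  df <- config$n_replicates - 1L
  tstat <- mean_r / (sd_r / sqrt(config$n_replicates))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[sd_r == 0 & mean_r != 0] <- 0
  p[sd_r == 0 & mean_r == 0] <- 1
  rownames(mean_r) <- gene_ids
  time_course_matrix(mean_r, p, timepoints)
}

#' Simulate promoter sequences with planted cis-element instances
#'
#' Every gene receives a random background promoter (i.i.d. draws from the
#' configured base composition, or a first-order chain when
#' `background_order > 0`); members of each cluster then receive one
#' concrete instance of the cluster's planted element pattern, at a uniform
#' random position and strand, with the configured per-cluster rate.
#'
#' @param universe a [generate_gene_universe()] table.
#' @param truth the `ground_truth` from [simulate_timecourse()].
#' @param config a [simulation_config()].
#' @return list with `sequences` (a `DNAStringSet` named by gene) and
#'   `instances` (data.frame of planted sites: gene, cluster, pattern,
#'   realized sequence, position, strand).
#' @export
simulate_promoters <- function(universe, truth, config) {
  with_seed(config$seed + 2L, {
    L <- config$promoter_length
    planted <- config$planted_motifs
    if (is.null(planted)) {
      planted <- data.frame(pattern = truth$clusters$pattern,
                            cluster = truth$clusters$cluster,
                            rate = config$planted_rate,
                            class = truth$clusters$regulator_class,
                            stringsAsFactors = FALSE)
    }
    if (any(nchar(planted$pattern) > L)) {
      stop("planted pattern longer than promoter")
    }
    if (any(planted$rate < 0 | planted$rate > 1)) {
      stop("occurrence rates must lie in [0, 1]")
    }
    n <- nrow(universe)
    base_mat <- sample_background(n, L, config)
    inst <- list()
    for (r in seq_len(nrow(planted))) {
      members <- truth$genes$gene_id[!is.na(truth$genes$cluster) &
                                       truth$genes$cluster == planted$cluster[r]]
      idx <- match(members, universe$gene_id)
      carry <- stats::runif(length(idx)) < planted$rate[r]
      for (i in idx[carry]) {
        s <- iupac_realize(planted$pattern[r])
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") s else iupac_revcomp(s)
        w <- nchar(ins)
        pos <- sample.int(L - w + 1L, 1L)
        base_mat[i, pos:(pos + w - 1L)] <- strsplit(ins, "")[[1]]
        inst[[length(inst) + 1L]] <- data.frame(
          gene = universe$gene_id[i], cluster = planted$cluster[r],
          pattern = planted$pattern[r], realized = s,
          position = pos, strand = strand, stringsAsFactors = FALSE)
      }
    }
    seqs <- apply(base_mat, 1L, paste, collapse = "")
    names(seqs) <- universe$gene_id
    list(sequences = Biostrings::DNAStringSet(seqs),
         instances = if (length(inst))
           do.call(rbind, c(inst, list(make.row.names = FALSE)))
         else data.frame(gene = character(0), cluster = character(0),
                         pattern = character(0), realized = character(0),
                         position = integer(0), strand = character(0)))
  })
}

sample_background <- function(n, L, config) {
  comp <- config$base_comp / sum(config$base_comp)
  if (config$background_order == 0L) {
    matrix(sample(BASES, n * L, replace = TRUE, prob = comp), n, L)
  } else {
    # first-order chain: a mild self-transition bias on top of the base
    # composition gives locally correlated background
    rho <- 0.1
    trans <- (1 - rho) * matrix(comp, 4, 4, byrow = TRUE) + rho * diag(4)
    out <- matrix("", n, L)
    state <- sample.int(4L, n, replace = TRUE, prob = comp)
    out[, 1L] <- BASES[state]
    for (j in 2:L) {
      u <- stats::runif(n)
      cum <- t(apply(trans[state, , drop = FALSE], 1L, cumsum))
      state <- max.col(u <= cum, ties.method = "first")
      out[, j] <- BASES[state]
    }
    out
  }
}

#' Simulate a QTL map with a planted transcription-factor enrichment
#'
#' Draws QTL intervals uniformly over the genome, then relocates each
#' upregulated TF gene so that it falls entirely inside the QTL union with
#' probability `min(1, qtl_enrichment_factor x genome coverage)` and
#' entirely outside otherwise. With factor 1 this reduces to the null.
#' Association flags for all genes are computed geometrically from the
#' final coordinates.
#'
#' @param universe a [generate_gene_universe()] table.
#' @param truth the `ground_truth` from [simulate_timecourse()].
#' @param config a [simulation_config()].
#' @return list with `qtl` (trait, chrom, start, end), `universe` (gene
#'   table with relocated up-TF coordinates) and `associations` (data.frame
#'   gene_id, associated flag).
#' @export
simulate_qtl_map <- function(universe, truth, config) {
  with_seed(config$seed + 3L, {
    lens <- config$chrom_lengths
    chrom <- sample(names(lens), config$n_qtl, replace = TRUE,
                    prob = lens / sum(lens))
    start <- vapply(chrom, function(ch) {
      sample.int(max(lens[[ch]] - config$qtl_width, 1L), 1L)
    }, numeric(1))
    qtl <- data.frame(trait = sample(QTL_TRAITS, config$n_qtl, replace = TRUE),
                      chrom = chrom, start = start,
                      end = pmin(start + config$qtl_width - 1, lens[chrom]),
                      stringsAsFactors = FALSE, row.names = NULL)
    union_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      qtl$chrom, IRanges::IRanges(qtl$start, qtl$end)))
    coverage <- sum(GenomicRanges::width(union_gr)) / sum(lens)
    p_in <- min(1, config$qtl_enrichment_factor * coverage)

    up_tf <- which(universe$gene_id %in%
                     truth$genes$gene_id[truth$genes$role == "up" &
                                           truth$genes$is_tf])
    seg_chrom <- as.character(GenomicRanges::seqnames(union_gr))
    seg_start <- GenomicRanges::start(union_gr)
    seg_w <- GenomicRanges::width(union_gr)
    for (i in up_tf) {
      glen <- universe$end[i] - universe$start[i] + 1L
      inside <- stats::runif(1) < p_in
      if (inside) {
        ok <- which(seg_w >= glen)
        s <- ok[sample.int(length(ok), 1L, prob = seg_w[ok])]
        pos <- seg_start[s] + sample.int(max(seg_w[s] - glen + 1L, 1L), 1L) - 1L
        universe$chrom[i] <- seg_chrom[s]
      } else {
        repeat {
          ch <- sample(names(lens), 1L, prob = lens / sum(lens))
          pos <- sample.int(max(lens[[ch]] - glen, 1L), 1L)
          cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos + glen - 1L))
          hit <- suppressWarnings(GenomicRanges::findOverlaps(cand, union_gr))
          if (length(hit) == 0L) break
        }
        universe$chrom[i] <- ch
      }
      universe$start[i] <- pos
      universe$end[i] <- pos + glen - 1L
      universe$tss[i] <- if (universe$strand[i] == "+") pos else pos + glen - 1L
    }
    coloc <- colocalize_genes(universe, qtl)
    associated <- universe$gene_id %in% coloc$associations$gene_id
    list(qtl = qtl, universe = universe,
         associations = data.frame(gene_id = universe$gene_id,
                                   associated = associated,
                                   stringsAsFactors = FALSE),
         coverage = coverage)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Single entry point tying the generator together: universe, both time
#' courses, promoters with planted elements, the packaged element catalog,
#' the QTL map, and the full ground truth. When `dir` is given the bundle
#' is also written to disk with a checksummed manifest (see
#' [write_study_bundle()]).
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @return a `study_bundle` list: `universe`, `chilling`, `h2o2`,
#'   `promoters`, `catalog`, `qtl`, `truth`, `config`.
#' @export
generate_study <- function(config = simulation_config(), dir = NULL) {
  universe <- generate_gene_universe(config)
  tc <- simulate_timecourse(universe, config)
  prom <- simulate_promoters(universe, tc$truth, config)
  qtl <- simulate_qtl_map(universe, tc$truth, config)
  tc$truth$qtl_associations <- qtl$associations
  bundle <- structure(list(
    universe = qtl$universe, chilling = tc$chilling, h2o2 = tc$h2o2,
    promoters = prom$sequences, planted_instances = prom$instances,
    catalog = load_element_catalog(), qtl = qtl$qtl, truth = tc$truth,
    config = config), class = "study_bundle")
  if (!is.null(dir)) write_study_bundle(bundle, dir)
  bundle
}
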