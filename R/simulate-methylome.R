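#' Parameters for the synthetic methylome generator
#'
#' Defaults emulate the nurse whole-bisulfite profile of a bumblebee-like
#' transcriptome: 23.14% of available cytosine sites in the CG context
#' (switch `context_mix` to the stingless-bee-like 15.44% via
#' `cg_fraction`), sparse methylation concentrated in CG, high site levels
#' at methylated sites (Beta(5,1)), and overdispersed coverage (negative
#' binomial, mean 30, dispersion 0.3) so that the 10x coverage filter is
#' consequential.
#'
#' @param n_transcripts Number of transcripts.
#' @param mean_length Mean transcript length (bp).
#' @param cg_fraction Fraction of available C sites in the CG context.
#' @param context_mix Probability vector over C-site dinucleotides
#'   `c(CG, CA, CC, CT)`; must sum to 1. Overrides `cg_fraction` if given.
#' @param p_meth Per-context per-site methylation probabilities
#'   `c(CG, CW, CC)` (transcript-level propensities average to these).
#' @param level_shape Beta shape parameters of the methylation level at a
#'   methylated site.
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage
#'   (`size = 1/dispersion`).
#' @param site_density Classified C sites (both strands) per bp.
#' @param expr_coupling_cg,expr_coupling_cw Strength of the log-linear
#'   coupling between a transcript's context-specific methylation
#'   propensity and its normalized read count (CG positive, CW zero by
#'   default, mirroring the observed sign pattern).
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#' @return A list of class `methylome_sim_params`.
#' @export
methylome_sim_params <- function(n_transcripts = 500L,
                                 mean_length = 1500L,
                                 cg_fraction = 0.2314,
                                 context_mix = NULL,
                                 p_meth = c(CG = 0.02, CW = 0.004, CC = 0.002),
                                 level_shape = c(5, 1),
                                 coverage_mean = 30,
                                 coverage_dispersion = 0.3,
                                 site_density = 0.2,
                                 expr_coupling_cg = 1.2,
                                 expr_coupling_cw = 0,
                                 seed = 1L) {
  if (is.null(context_mix)) {
    # split the non-CG mass over CA/CC/CT in fixed field-plausible ratio
    rest <- 1 - cg_fraction
    context_mix <- c(CG = cg_fraction, CA = rest * 0.47, CC = rest * 0.17,
      CT = rest * 0.36)
  }
  context_mix <- context_mix[c("CG", "CA", "CC", "CT")]
  if (anyNA(context_mix) || any(context_mix < 0)) {
    param_error("context_mix needs non-negative CG, CA, CC, CT entries")
  }
  if (abs(sum(context_mix) - 1) > 1e-8) {
    param_error("context_mix must sum to 1")
  }
  if (any(p_meth < 0 | p_meth > 1)) param_error("p_meth must lie in [0, 1]")
  structure(
    list(
      n_transcripts = as.integer(n_transcripts),
      mean_length = as.integer(mean_length),
      context_mix = context_mix, p_meth = p_meth,
      level_shape = level_shape, coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      site_density = site_density,
      expr_coupling_cg = expr_coupling_cg,
      expr_coupling_cw = expr_coupling_cw,
      seed = check_seed(seed)
    ),
    class = "methylome_sim_params"
  )
}

#' Simulate a transcriptome methylome with known truth
#'
#' Generates (i) a FASTA-ready transcriptome whose realized both-strand
#' C-site context census is a multinomial draw from `context_mix`, (ii) a
#' CGmap table of per-site methylation calls consistent with the sequence
#' dinucleotides on both strands, and (iii) a per-transcript truth table
#' sufficient to score every downstream estimator.
#'
#' Sequences are built from an A/T background with planted context motifs:
#' CG sites are planted as palindromic `CG` dinucleotides (a CpG on one
#' strand implies the CpG on the other, so CG sites come in strand pairs;
#' the generator draws the total CG-site count and emits half as many
#' motifs), CA/CT sites as `CA`/`CT`, and CC sites as `CCN` so that exactly
#' one defined CC site results. Methylation state is drawn per site with a
#' per-transcript, per-context propensity; methylated sites draw their
#' level from a Beta distribution, unmethylated sites have level 0.
#' Normalized read counts are generated log-linearly coupled to the
#' transcript's CG methylation propensity (and, optionally, CW).
#'
#' Sites with zero simulated coverage are unobserved and omitted from the
#' CGmap (they remain in the truth site counts).
#'
#' @param params A [methylome_sim_params()] object.
#' @return A list with `fasta` (tibble `seq_id`/`sequence`), `cgmap`
#'   (CGmap tibble), `truth` (per-transcript tibble: site and methylation
#'   counts per class, true mean level, propensities, `norm_count`) and
#'   `params`.
#' @export
simulate_methylome <- function(params = methylome_sim_params()) {
  stopifnot(inherits(params, "methylome_sim_params"))
  set.seed(params$seed)
  p <- params
  n <- p$n_transcripts
  lens <- pmax(200L, round(stats::rgamma(n, shape = 4, scale = p$mean_length / 4)))
  u_cg <- runif(n)   # CG methylation propensity scaler
  u_cw <- runif(n)   # CW methylation propensity scaler

  fasta_rows <- vector("list", n)
  cgmap_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  size_nb <- 1 / p$coverage_dispersion

  for (i in seq_len(n)) {
    id <- sprintf("st%04d", i)
    m_target <- max(4L, round(lens[[i]] * p$site_density))
    cts <- as.integer(rmultinom(1L, m_target, p$context_mix)[, 1L])
    names(cts) <- names(p$context_mix)
    n_pairs <- as.integer(round(cts[["CG"]] / 2))
    motifs <- c(
      rep("CG", n_pairs), rep("CA", cts[["CA"]]),
      rep("CCN", cts[["CC"]]), rep("CT", cts[["CT"]])
    )
    motifs <- sample(motifs)
    n_mot <- length(motifs)
    motif_len <- nchar(motifs)
    spacer_total <- max(0L, lens[[i]] - sum(motif_len))
    gap_w <- as.integer(rmultinom(1L, spacer_total, rep(1, n_mot + 1L))[, 1L])
    spacers <- vapply(gap_w, function(w) {
      if (w == 0L) "" else paste(sample(c("A", "T"), w, replace = TRUE), collapse = "")
    }, character(1))
    seq_parts <- character(2L * n_mot + 1L)
    seq_parts[seq(1L, 2L * n_mot + 1L, by = 2L)] <- spacers
    seq_parts[seq(2L, 2L * n_mot, by = 2L)] <- motifs
    sequence <- paste(seq_parts, collapse = "")
    # motif start offsets (1-based)
    part_len <- nchar(seq_parts)
    starts <- cumsum(c(1L, part_len[-length(part_len)]))
    motif_start <- starts[seq(2L, 2L * n_mot, by = 2L)]

    # expand motifs to site records
    site_pos <- integer(0); site_nuc <- character(0); site_dinuc <- character(0)
    for (j in seq_len(n_mot)) {
      o <- motif_start[[j]]
      mt <- motifs[[j]]
      if (mt == "CG") {
        site_pos <- c(site_pos, o, o + 1L)
        site_nuc <- c(site_nuc, "C", "G")
        site_dinuc <- c(site_dinuc, "CG", "CG")
      } else if (mt == "CCN") {
        site_pos <- c(site_pos, o)
        site_nuc <- c(site_nuc, "C")
        site_dinuc <- c(site_dinuc, "CC")
      } else {
        site_pos <- c(site_pos, o)
        site_nuc <- c(site_nuc, "C")
        site_dinuc <- c(site_dinuc, mt)
      }
    }
    cls <- context_class(site_dinuc)
    p_site <- c(
      CG = min(1, 2 * u_cg[[i]] * p$p_meth[["CG"]]),
      CW = min(1, 2 * u_cw[[i]] * p$p_meth[["CW"]]),
      CC = p$p_meth[["CC"]]
    )[cls]
    meth <- runif(length(cls)) < p_site
    level_true <- ifelse(meth,
      rbeta(length(cls), p$level_shape[[1L]], p$level_shape[[2L]]), 0)
    coverage <- rnbinom(length(cls), mu = p$coverage_mean, size = size_nb)
    mc <- rbinom(length(cls), coverage, level_true)
    obs <- coverage > 0L
    ord <- order(site_pos)

    fasta_rows[[i]] <- tibble(seq_id = id, sequence = sequence)
    cg <- tibble(
      seq_id = id, nucleotide = site_nuc, position = site_pos,
      context3 = ifelse(site_dinuc == "CG", "CG", "CHH"),
      dinucleotide = site_dinuc,
      level = ifelse(coverage > 0L, round(mc / pmax(coverage, 1L), 2), 0),
      mc_count = as.integer(mc), coverage = as.integer(coverage)
    )[ord, ][obs[ord], ]
    cgmap_rows[[i]] <- cg
    truth_rows[[i]] <- tibble(
      seq_id = id, length = nchar(sequence),
      n_sites = length(cls),
      n_cg = sum(cls == "CG"), n_cw = sum(cls == "CW"), n_cc = sum(cls == "CC"),
      n_meth = sum(meth),
      n_meth_cg = sum(meth & cls == "CG"),
      n_meth_cw = sum(meth & cls == "CW"),
      n_meth_cc = sum(meth & cls == "CC"),
      true_mean_mc = 100 * mean(level_true),
      u_cg = u_cg[[i]], u_cw = u_cw[[i]]
    )
  }
  truth <- bind_rows(truth_rows)
  truth$norm_count <- rlnorm(
    n,
    meanlog = log(100) +
      p$expr_coupling_cg * (truth$u_cg - 0.5) +
      p$expr_coupling_cw * (truth$u_cw - 0.5),
    sdlog = 0.6
  )
  list(
    fasta = bind_rows(fasta_rows),
    cgmap = bind_rows(cgmap_rows),
    truth = truth,
    params = params
  )
}
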