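# Seeded generator of paired multi-view study analogues with planted
# ground truth. Each subject carries a latent factor z; at day 10 the
# factor mean is shifted by `effect` (in sd units) in the treated group,
# at day 0 both groups are null. Informative features load on z with
# weight rho plus Normal(0, noise_sd) noise; noise features are
# standard normal. The three views then receive view-appropriate
# measurement models: lognormal intensities, softmax + multinomial
# compositional counts, and negative-binomial counts (day 10 only).

#' Specification of a synthetic multi-view study
#'
#' Defaults mirror a two-arm design with 9 subjects per group, paired
#' day-0/day-10 sampling for the intensity and compositional views and
#' day-10-only sampling for the count view; feature-space sizes 300 /
#' 150 / 500 with 8 / 4 / 17 informative features.
#'
#' @param n_per_group Subjects per arm.
#' @param p Named integer vector: features per view
#'   (metabolome, microbiome, exfoliome analogues).
#' @param k Informative features per view.
#' @param effect Latent group mean shift at day 10, in sd units of the
#'   latent factor.
#' @param rho Loading of informative features on the latent factor.
#' @param noise_sd Residual sd of informative features around their
#'   latent loading. The default 0.15 makes informative features within
#'   a view strongly mutually correlated
#'   (\eqn{\rho^2/(\rho^2 + \sigma^2) \approx 0.97}), emulating the
#'   tight redundant feature clusters (e.g. co-expressed genes at
#'   R > 0.95) that the consensus rule's correlation augmentation
#'   targets.
#' @param depth Sequencing depth of the compositional view.
#' @param nb_dispersion Negative-binomial dispersion of the count view
#'   (variance \eqn{\mu + \phi \mu^2}).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_group = 9L,
                           p = c(metabolome = 300L, microbiome = 150L,
                                 exfoliome = 500L),
                           k = c(metabolome = 8L, microbiome = 4L,
                                 exfoliome = 17L),
                           effect = 2.0, rho = 0.8, noise_sd = 0.15,
                           depth = 1e4, nb_dispersion = 0.5, seed = 1L) {
  mvc_assert(n_per_group >= 2L, "config_error", "need at least 2 subjects per group")
  mvc_assert(length(p) == 3L && length(k) == 3L, "config_error",
             "p and k must give one value per view")
  if (is.null(names(p))) names(p) <- c("metabolome", "microbiome", "exfoliome")
  names(k) <- names(p)
  mvc_assert(all(k <= p), "config_error", "k must not exceed p in any view")
  mvc_assert(all(k >= 1L), "config_error", "each view needs at least 1 informative feature")
  mvc_assert(effect >= 0, "config_error", "effect must be non-negative")
  mvc_assert(rho >= 0 && rho <= 1, "config_error", "rho must lie in [0, 1]")
  mvc_assert(noise_sd >= 0, "config_error", "noise_sd must be non-negative")
  mvc_assert(depth >= 1, "config_error", "depth must be positive")
  mvc_assert(nb_dispersion > 0, "config_error", "nb_dispersion must be positive")
  mvc_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "config_error", "seed must be a single integer")
  structure(list(n_per_group = as.integer(n_per_group),
                 p = stats::setNames(as.integer(p), names(p)),
                 k = stats::setNames(as.integer(k), names(p)),
                 effect = effect, rho = rho, noise_sd = noise_sd,
                 depth = depth, nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

softmax_rows <- function(L) {
  E <- exp(sweep(L, 1L, apply(L, 1L, max), "-"))
  sweep(E, 1L, rowSums(E), "/")
}

#' Simulate a paired multi-view study with planted truth
#'
#' Per subject i, latent \eqn{z_i \sim N(group_i \cdot effect, 1)} at
#' day 10 and \eqn{z_i^{(0)} \sim N(0, 1)} at day 0 (both groups null at
#' baseline, so paired differencing preserves the planted signal).
#' Signal matrices have informative columns
#' \eqn{\rho z + N(0, noise\_sd)} and noise columns \eqn{N(0,1)}; the
#' metabolome analogue is exponentiated to lognormal intensities, the
#' microbiome analogue passes through a per-feature baseline + softmax
#' and multinomial sampling at the given depth, the exfoliome analogue
#' becomes negative-binomial counts via an exp link (day-10 samples
#' only). Fully reproducible from `spec$seed`; the caller's RNG state
#' is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A `multiomic_study`: `views` (named [feature_table()]s),
#'   `design` ([study_design()]) and `truth` (informative ids per view,
#'   latent factors, group labels).
#' @export
simulate_multiomic <- function(spec = synthetic_spec()) {
  mvc_assert(inherits(spec, "synthetic_spec"), "config_error",
             "spec must come from synthetic_spec()")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- 2L * spec$n_per_group
  subjects <- sprintf("S%02d", seq_len(n))
  group <- rep(0:1, each = spec$n_per_group)
  z10 <- stats::rnorm(n, mean = group * spec$effect, sd = 1)
  z0 <- stats::rnorm(n, mean = 0, sd = 1)

  feat_ids <- mapply(function(vn, pd) sprintf("%s_%03d", substr(vn, 1L, 3L),
                                              seq_len(pd)),
                     names(spec$p), spec$p, SIMPLIFY = FALSE)
  informative <- mapply(function(ids, kd) sort(sample(ids, kd)),
                        feat_ids, spec$k, SIMPLIFY = FALSE)

  signal_matrix <- function(z, vn) {
    pd <- spec$p[[vn]]
    ids <- feat_ids[[vn]]
    S <- matrix(stats::rnorm(n * pd), n, pd, dimnames = list(subjects, ids))
    info <- ids %in% informative[[vn]]
    S[, info] <- spec$rho * z +
      matrix(stats::rnorm(n * sum(info), sd = spec$noise_sd), n, sum(info))
    S
  }

  day_ids <- function(day) paste0(subjects, "_d", day)

  # metabolome analogue: lognormal intensities, both days
  met10 <- exp(signal_matrix(z10, "metabolome"))
  met0 <- exp(signal_matrix(z0, "metabolome"))
  rownames(met10) <- day_ids(10)
  rownames(met0) <- day_ids(0)
  metabolome <- feature_table(rbind(met0, met10), "intensities")

  # microbiome analogue: baseline + signal logits -> softmax -> multinomial
  pd <- spec$p[["microbiome"]]
  base <- stats::rnorm(pd, sd = 1.5)
  base[feat_ids$microbiome %in% informative$microbiome] <- 0
  draw_counts <- function(z, day) {
    L <- sweep(signal_matrix(z, "microbiome"), 2L, base, "+")
    P <- softmax_rows(L)
    counts <- t(apply(P, 1L, function(pr) stats::rmultinom(1L, spec$depth, pr)))
    dimnames(counts) <- list(paste0(subjects, "_d", day), feat_ids$microbiome)
    counts
  }
  microbiome <- feature_table(rbind(draw_counts(z0, 0), draw_counts(z10, 10)),
                              "counts")

  # exfoliome analogue: NB counts via exp link, day 10 only
  mu <- exp(signal_matrix(z10, "exfoliome") + log(20))
  exfo <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                 nrow = n, dimnames = list(day_ids(10), feat_ids$exfoliome))
  exfoliome <- feature_table(exfo, "counts")

  design <- study_design(data.frame(
    sample_id = c(day_ids(0), day_ids(10)),
    subject_id = rep(subjects, 2L),
    group = rep(group, 2L),
    day = rep(c(0L, 10L), each = n),
    stringsAsFactors = FALSE))

  structure(list(views = list(metabolome = metabolome,
                              microbiome = microbiome,
                              exfoliome = exfoliome),
                 design = design,
                 truth = list(informative = informative,
                              z_day10 = stats::setNames(z10, subjects),
                              z_day0 = stats::setNames(z0, subjects),
                              labels = stats::setNames(group, subjects)),
                 spec = spec),
            class = "multiomic_study")
}

#' @export
print.multiomic_study <- function(x, ...) {
  cat(sprintf("multiomic_study: %d subjects (%d per group), views: %s\n",
              2L * x$spec$n_per_group, x$spec$n_per_group,
              paste(sprintf("%s (%d samples x %d features)",
                            names(x$views),
                            vapply(x$views, n_samples, integer(1)),
                            vapply(x$views, n_features, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' The repository's end-to-end study analogue
#'
#' [simulate_multiomic()] with all defaults and seed 20240415: 18
#' subjects, three views, truth sets of sizes 8 / 4 / 17.
#'
#' @return A `multiomic_study`.
#' @export
default_study_analogue <- function() {
  simulate_multiomic(synthetic_spec(seed = 20240415L))
}
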