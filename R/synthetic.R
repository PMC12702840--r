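#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the package is designed for: 4408
#' adults; outcome priors 85.0% non-MAFLD, 11.5% nondiabetic MAFLD, 3.5%
#' diabetic MAFLD; feature-group sizes 2/36/32/42; two latent subclusters per
#' outcome class (intraphenotype variability); survey-only missingness.
#'
#' @param n Cohort size.
#' @param priors Length-3 class priors, must sum to 1.
#' @param k_sub Subclusters per class.
#' @param rho Cross-view coupling strength in `[0, 1]`: 0 makes the survey
#'   features pure noise; 1 couples them maximally to the latent factors
#'   (and hence to the outcome and the clinical view).
#' @param missing_rate MCAR missingness rate on survey cells, in `[0, 1)`.
#' @param nonresponse_rate Probability, per person and per survey view
#'   independently, of skipping that survey entirely (block missingness on
#'   top of the cell-level rate); self-reported instruments are routinely
#'   answered by only part of a cohort.
#' @param n_clinical,n_lifestyle,n_genetic Feature counts per group.
#' @param lifestyle_levels,genetic_levels Coded levels per survey feature.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 4408,
                             priors = c(0.850, 0.115, 0.035),
                             k_sub = 2,
                             rho = 0.8,
                             missing_rate = 0.30,
                             nonresponse_rate = 0.25,
                             n_clinical = 36,
                             n_lifestyle = 32,
                             n_genetic = 42,
                             lifestyle_levels = 4,
                             genetic_levels = 3,
                             seed = 1L) {
  stopifnot(length(priors) == 3, all(priors >= 0),
            abs(sum(priors) - 1) < 1e-8,
            rho >= 0, rho <= 1,
            missing_rate >= 0, missing_rate < 1,
            nonresponse_rate >= 0, nonresponse_rate < 1,
            k_sub >= 1, n >= 1, n_clinical >= 2)
  structure(list(n = n, priors = priors, k_sub = k_sub, rho = rho,
                 missing_rate = missing_rate,
                 nonresponse_rate = nonresponse_rate,
                 n_clinical = n_clinical,
                 n_lifestyle = n_lifestyle, n_genetic = n_genetic,
                 lifestyle_levels = as.integer(lifestyle_levels),
                 genetic_levels = as.integer(genetic_levels),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Latent-factor geometry. Six factors: dims 1-3 form the metabolic axis
# (expressed in the clinical view), dims 3-6 the behavioural/hereditary axis
# (expressed in the survey views). Dim 3 is shared, coupling the views beyond
# the outcome itself. Class centres separate on both axes so the survey views
# carry class signal complementary to the clinical view.
.latent_dim <- 6L

.class_centres <- function() {
  delta <- 0.8
  rbind(c(0, 0, 0, 0, 0, 0),
        c(1, 1, 0, 1, 1, 0) * delta,
        c(0, 1, 1, 0, 1, 1) * delta)
}

#' Generate a synthetic cohort with planted structure
#'
#' Each person gets a class from the priors and a subcluster within the
#' class; the pair indexes a centre in a 6-dimensional latent factor space,
#' around which the person's latent vector is drawn. Numeric clinical
#' features are noisy linear readouts of the metabolic factors
#' (class/subcluster-shifted Gaussians); the first two clinical features are
#' definitive diabetic markers, elevated only in the diabetic class.
#' Categorical survey features are drawn from a softmax over level scores
#' `rho * <w_level, u>`, so they carry class signal iff `rho > 0`. Whole
#' survey views are then masked for non-responders at `nonresponse_rate`
#' and remaining survey cells MCAR at `missing_rate`.
#'
#' @param config A [synthetic_config()].
#' @return List with `table` (a [cohort_table()]) and `truth` (per-person
#'   `class` index 0/1/2, `subcluster`, latent matrix `u`; per-feature
#'   loadings).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- .latent_dim
  schema <- default_schema(n_clinical = config$n_clinical,
                           n_lifestyle = config$n_lifestyle,
                           n_genetic = config$n_genetic,
                           lifestyle_levels = config$lifestyle_levels,
                           genetic_levels = config$genetic_levels)
  out <- with_seed(config$seed, {
    n <- config$n
    cls <- sample.int(3, n, replace = TRUE, prob = config$priors) - 1L
    if (any(tabulate(cls + 1L, 3L) == 0))
      warning("a class is absent from the generated cohort (small n or ",
              "degenerate priors)", call. = FALSE)
    sub <- sample.int(config$k_sub, n, replace = TRUE)

    centres <- .class_centres()
    # subcluster offsets: per class a random direction over dims 2-6,
    # subclusters sitting at +/- 1 along it, so each class is bimodal
    # (intraphenotype variability) around its centre.
    off <- array(0, dim = c(3, config$k_sub, L))
    for (c in 1:3) {
      v <- c(0, stats::rnorm(L - 1L))
      v <- 1.0 * v / sqrt(sum(v^2))
      for (s in seq_len(config$k_sub))
        off[c, s, ] <- v * (2 * (s %% 2) - 1) * ceiling(s / 2)
    }
    u <- centres[cls + 1L, , drop = FALSE] +
      t(vapply(seq_len(n), function(i) off[cls[i] + 1L, sub[i], ],
               numeric(L))) +
      matrix(stats::rnorm(n * L, sd = 1.0), n, L)

    # clinical view: strong readouts of the metabolic dims 1-3 plus weak
    # traces of the behavioural dims 4-6 (lifestyle leaves mild clinical
    # marks, which is what lets cross-view alignment denoise rather than
    # discard the survey signal), noise sd 2.5
    p_c <- config$n_clinical
    B_C <- matrix(0, L, p_c)
    B_C[1:3, ] <- matrix(stats::rnorm(3 * p_c, sd = 1 / sqrt(3)), 3, p_c)
    B_C[4:6, ] <- matrix(stats::rnorm(3 * p_c, sd = 0.3 / sqrt(3)), 3, p_c)
    clin <- u %*% B_C + matrix(stats::rnorm(n * p_c, sd = 2.5), n, p_c)
    # definitive diabetic markers: elevated in class 2 only
    B_C[, 1:2] <- 0
    clin[, 1] <- stats::rnorm(n) + 1.5 * (cls == 2L)
    clin[, 2] <- stats::rnorm(n) + 1.5 * (cls == 2L)

    # survey views: each feature draws its level from a softmax over
    # per-level scores on the behavioural dims 3-6, scaled by rho
    survey_dims <- 3:6
    draw_survey <- function(n_feat, J) {
      W <- array(stats::rnorm(n_feat * J * L, sd = 1.5) *
                   rep(seq_len(L) %in% survey_dims, each = n_feat * J),
                 dim = c(n_feat, J, L))
      vals <- matrix(1L, n, n_feat)
      for (f in seq_len(n_feat)) {
        logits <- config$rho * u %*% t(W[f, , ])   # n x J
        P <- row_softmax(logits)
        cum <- t(apply(P, 1, cumsum))
        r <- stats::runif(n)
        vals[, f] <- 1L + rowSums(r > cum)
      }
      list(vals = vals, W = W)
    }
    lif <- draw_survey(config$n_lifestyle, config$lifestyle_levels)
    gen <- draw_survey(config$n_genetic, config$genetic_levels)

    age <- round(stats::rnorm(n, mean = 58.18, sd = 12.94) + 2 * cls, 1)
    sex <- ifelse(stats::runif(n) < 0.681, "female", "male")

    list(cls = cls, sub = sub, u = u, B_C = B_C, clin = clin,
         lif = lif, gen = gen, age = age, sex = sex)
  })

  lev <- function(J) paste0("L", seq_len(J))
  dat <- data.frame(age = out$age, sex = out$sex, stringsAsFactors = FALSE)
  clin <- as.data.frame(out$clin)
  colnames(clin) <- schema_features(schema, "C")
  lifd <- as.data.frame(lapply(seq_len(config$n_lifestyle), function(f)
    lev(config$lifestyle_levels)[out$lif$vals[, f]]),
    col.names = schema_features(schema, "S_lif"))
  gend <- as.data.frame(lapply(seq_len(config$n_genetic), function(f)
    lev(config$genetic_levels)[out$gen$vals[, f]]),
    col.names = schema_features(schema, "S_gen"))
  dat <- cbind(dat, clin, lifd, gend)
  y <- mafld_classes()[out$cls + 1L]
  table <- cohort_table(dat, y, schema)
  if (config$nonresponse_rate > 0)
    table <- inject_nonresponse(table, config$nonresponse_rate,
                                seed = config$seed + 2L)
  if (config$missing_rate > 0)
    table <- inject_missingness(table, config$missing_rate,
                                seed = config$seed + 1L)
  truth <- list(class = out$cls, subcluster = out$sub, u = out$u,
                clinical_loadings = out$B_C,
                lifestyle_loadings = out$lif$W,
                genetic_loadings = out$gen$W)
  list(table = table, truth = truth)
}

#' Mask survey cells completely at random
#'
#' Applies an MCAR mask at rate `m` to the lifestyle and genetic family
#' history cells only; demographics, clinical features and labels are never
#' masked.
#'
#' @param table A [cohort_table()].
#' @param m Missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `cohort_table` with the additional mask applied.
#' @export
#' Mask whole survey views for non-responding persons
#'
#' Each person skips each survey view (lifestyle; genetic family history)
#' independently with probability `rate`, masking every cell of that view's
#' feature group for that person. Models survey nonparticipation, the block
#' analogue of cell-level missingness.
#'
#' @param table A [cohort_table()].
#' @param rate Per-person, per-view nonresponse probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `cohort_table` with the block mask applied.
#' @export
inject_nonresponse <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1)
    stop("nonresponse rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(table)
  n <- nrow(table$data)
  mask <- table$mask
  dat <- table$data
  groups <- list(schema_features(table$schema, "S_lif"),
                 schema_features(table$schema, "S_gen"))
  skip <- with_seed(seed, matrix(stats::runif(2 * n) < rate, n, 2))
  for (g in 1:2) {
    rows <- which(skip[, g])
    mask[rows, groups[[g]]] <- TRUE
    for (nm in groups[[g]]) dat[[nm]][rows] <- NA
  }
  structure(list(data = dat, y = table$y, mask = mask, schema = table$schema),
            class = "cohort_table")
}

inject_missingness <- function(table, m, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.numeric(m) || length(m) != 1 || m < 0 || m >= 1)
    stop("missing rate m must lie in [0, 1)", call. = FALSE)
  if (m == 0) return(table)
  survey <- schema_features(table$schema, c("S_lif", "S_gen"))
  n <- nrow(table$data)
  hit <- with_seed(seed,
    matrix(stats::runif(n * length(survey)) < m, n, length(survey)))
  mask <- table$mask
  mask[, survey] <- mask[, survey] | hit
  dat <- table$data
  for (j in seq_along(survey)) dat[[survey[j]]][hit[, j]] <- NA
  structure(list(data = dat, y = table$y, mask = mask, schema = table$schema),
            class = "cohort_table")
}
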