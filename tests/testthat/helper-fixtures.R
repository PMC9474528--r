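# Shared in-code fixtures. Everything is generated at test time; expensive
# artefacts are built once per session and memoised here.

PET_SPACING <- c(3.18, 3.18, 3.0)

rand_volume <- function(d = c(8, 8, 8), spacing = PET_SPACING, seed = 1,
                        lo = 0, hi = 10) {
  petclust:::with_seed(seed,
    image_volume(array(stats::runif(prod(d), lo, hi), d), spacing))
}

full_mask <- function(volume) {
  voi_mask(array(TRUE, dim(volume$data)), volume$spacing, volume$origin)
}

rand_region <- function(d = c(6, 6, 6), ng = 4, seed = 1,
                        spacing = PET_SPACING, frac = 0.8) {
  petclust:::with_seed(seed, {
    vol <- image_volume(array(stats::runif(prod(d), 0, ng), d), spacing)
    m <- array(stats::runif(prod(d)) < frac, d)
    m[1, 1, 1] <- TRUE
    list(volume = vol, mask = voi_mask(m, spacing))
  })
}

# small noise-free spherical phantom for analytic checks
sphere_phantom <- function(radius_mm = 10, amp = 8, bg = 1,
                           dim3 = c(32, 32, 32), spacing = PET_SPACING) {
  params <- cluster_sim_params()
  sig2 <- params$profile_sigma^2
  r2 <- petclust:::ellipsoid_r2(dim3, spacing, c(0, 0, 0), rep(radius_mm, 3))
  g <- exp(-r2 / (2 * sig2))
  g[r2 > 4] <- 0
  image_volume(pmax(bg + (amp - bg) * g, 0), spacing,
               -(dim3 - 1) / 2 * spacing)
}

# session-memoised small extracted cohort (used by several test files)
.fixture_env <- new.env(parent = emptyenv())

small_cohort_features <- function() {
  if (is.null(.fixture_env$feats)) {
    p <- cluster_sim_params()
    p$simulate_ct <- FALSE
    cohort <- simulate_cohort(4, 5, 3, p, seed = 2024)
    .fixture_env$feats <- suppressWarnings(
      extract_cohort(cohort, modalities = "PET"))
  }
  .fixture_env$feats
}

# synthetic feature table with planted class signal (no imaging involved);
# cheap input for classifier / sham behaviour tests
toy_feature_table <- function(n1 = 12, n2 = 14, ns = 8, p = 20, delta = 2,
                              seed = 99) {
  petclust:::with_seed(seed, {
    cl <- c(rep("cluster1", n1), rep("cluster2", n2), rep("sporadic", ns))
    n <- length(cl)
    shift <- ifelse(cl == "cluster1", delta, ifelse(cl == "sporadic",
                                                    delta / 2, 0))
    x <- matrix(stats::rnorm(n * p), n, p) + shift
    colnames(x) <- paste0("PET_f", seq_len(p))
    colnames(x)[1] <- "PET_firstorder_Maximum"
    data.frame(id = sprintf("les%02d", 1:n), cluster = cl,
               adrenergic = stats::runif(n) < ifelse(cl == "cluster2", .8, .2),
               noradrenergic = stats::runif(n) < .5,
               dopaminergic = stats::runif(n) < .15,
               x, check.names = FALSE)
  })
}
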