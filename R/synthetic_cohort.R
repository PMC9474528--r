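# Phantom PET/CT lesion simulator.
#
# The generator states the world the pipeline is tested in: a 40-lesion
# cohort (13 cluster 1 / 18 cluster 2 / 9 sporadic) in which cluster 1
# lesions show higher uptake, larger size and more heterogeneous texture
# than cluster 2 and sporadic lesions, with pooled SUVmax and metabolic
# tumour volume comparable to the clinical ranges, plus dichotomous
# adrenergic / noradrenergic / dopaminergic biochemistry flags.

#' Default simulation parameters for the synthetic PPGL cohort
#'
#' Per-cluster lognormal distributions for peak amplitude (g/mL) and
#' equivalent-sphere radius (mm), a 0-1 texture-heterogeneity weight, a
#' necrotic-core probability, Bernoulli probabilities for the three
#' biochemistry flags, plus global background SUV, PET noise, CT contrast
#' and grid definitions.
#'
#' Sporadic lesions draw their imaging parameters from a mixture:
#' `sporadic_mix_c2` (default 0.75) of draws use the cluster-2 parameter
#' set, the rest the cluster-1 set, so sporadic lesions frequently resemble
#' cluster 2 and occasionally cluster 1. `effect_scale` linearly
#' interpolates the cluster-1 log-medians, heterogeneity and necrosis rate
#' between the cluster-2 baseline (`effect_scale = 0`, clusters
#' indistinguishable) and the full default separation (`effect_scale = 1`).
#'
#' Biochemistry defaults are solved once so that the pooled expected
#' positives at the 13/18/9 design match the clinical marginals 17 / 24 / 6
#' of 40 (adrenergic / noradrenergic / dopaminergic).
#'
#' @param effect_scale numeric in \[0, 1\]; planted cluster-1 effect size.
#' @return A list of class `cluster_sim_params`.
#' @export
cluster_sim_params <- function(effect_scale = 1) {
  stopifnot(is.numeric(effect_scale), effect_scale >= 0, effect_scale <= 1)
  c2 <- list(
    amp_meanlog = log(4), amp_sdlog = 0.40,
    radius_meanlog = log(16), radius_sdlog = 0.28,
    heterogeneity = 0.15, necrosis_prob = 0.05,
    biochem = c(adrenergic = 0.80, noradrenergic = 0.35, dopaminergic = 0.02)
  )
  c1_full <- list(
    amp_meanlog = log(10), amp_sdlog = 0.45,
    radius_meanlog = log(24), radius_sdlog = 0.28,
    heterogeneity = 0.50, necrosis_prob = 0.30,
    biochem = c(adrenergic = 0.10, noradrenergic = 0.90, dopaminergic = 0.35)
  )
  s <- effect_scale
  c1 <- c1_full
  for (f in c("amp_meanlog", "radius_meanlog", "heterogeneity",
              "necrosis_prob"))
    c1[[f]] <- c2[[f]] + s * (c1_full[[f]] - c2[[f]])
  c1$amp_sdlog <- c2$amp_sdlog + s * (c1_full$amp_sdlog - c2$amp_sdlog)
  p <- list(
    clusters = list(cluster1 = c1, cluster2 = c2),
    sporadic_biochem = c(adrenergic = 0.20, noradrenergic = 0.65,
                         dopaminergic = 0.10),
    sporadic_mix_c2 = 0.75,
    sporadic_shift = 0.30,   # sporadic components sit between the clusters

    background_suv = 1.0,
    pet_noise_sd = 0.15,
    texture_logsd = 0.40,       # log-sd of the multiplicative field at weight 1
    necrosis_depth = 0.70,      # central uptake reduction for necrotic cores
    radius_limits = c(9, 30),   # mm, keeps delineation and runtime sane
    aniso_range = c(0.85, 1.18),
    profile_sigma = 1 / sqrt(2 * log(1 / 0.41)),  # 41% of amplitude at r = R
    pet_dim = c(64L, 64L, 64L), pet_spacing = c(3.18, 3.18, 3.0),
    ct_dim = c(128L, 128L, 48L), ct_spacing = c(0.98, 0.98, 3.0),
    ct_lesion_hu_mean = 45, ct_lesion_hu_sd = 8,
    ct_background_hu_mean = 30, ct_background_hu_sd = 18,
    ct_texture_scale = 20,
    simulate_ct = TRUE,
    distractor = FALSE,          # adjacent high-uptake blob (kidney surrogate)
    distractor_offset_mm = c(60, 60, 0),
    distractor_radius_mm = 12,
    distractor_amplitude = 8
  )
  class(p) <- c("cluster_sim_params", "list")
  p
}

valid_clusters <- c("cluster1", "cluster2", "sporadic")

#' Draw the latent lesion parameters for one cluster
#'
#' The scalar draws behind [simulate_lesion()], exposed so that the
#' configured effect directions can be checked cheaply by Monte Carlo
#' without synthesising voxel data.
#'
#' @param cluster one of `"cluster1"`, `"cluster2"`, `"sporadic"`.
#' @param params a [cluster_sim_params()] list.
#' @return List with `amplitude`, `radii` (3, mm), `heterogeneity`,
#'   `necrotic`, `component` (the parameter set actually used).
#' @export
draw_lesion_params <- function(cluster, params = cluster_sim_params()) {
  cluster <- match.arg(cluster, valid_clusters)
  component <- cluster
  if (cluster == "sporadic")
    component <- if (stats::runif(1) < params$sporadic_mix_c2) "cluster2"
    else "cluster1"
  cp <- params$clusters[[component]]
  if (cluster == "sporadic") {
    # sporadic lesions resemble -- but do not duplicate -- the cluster the
    # component was drawn from: shift part-way towards the other cluster
    other <- params$clusters[[setdiff(c("cluster1", "cluster2"), component)]]
    w <- params$sporadic_shift %||% 0
    for (f in c("amp_meanlog", "amp_sdlog", "radius_meanlog",
                "radius_sdlog", "heterogeneity", "necrosis_prob"))
      cp[[f]] <- (1 - w) * cp[[f]] + w * other[[f]]
  }
  amp <- NA_real_
  for (i in 1:100) {
    amp <- stats::rlnorm(1, cp$amp_meanlog, cp$amp_sdlog)
    if (amp > params$background_suv) break
    amp <- NA_real_
  }
  if (is.na(amp))
    stop("could not draw an amplitude above background in 100 attempts")
  r <- stats::rlnorm(1, cp$radius_meanlog, cp$radius_sdlog)
  r <- min(max(r, params$radius_limits[1]), params$radius_limits[2])
  aniso <- stats::runif(3, params$aniso_range[1], params$aniso_range[2])
  list(amplitude = amp, radii = r * aniso,
       heterogeneity = cp$heterogeneity,
       necrotic = stats::runif(1) < cp$necrosis_prob,
       component = component)
}

# Centred voxel-centre coordinate vectors for a grid.
grid_coords <- function(dm, spacing) {
  lapply(1:3, function(k) (seq_len(dm[k]) - (dm[k] + 1) / 2) * spacing[k])
}

# Squared normalised ellipsoidal radius field on a grid.
ellipsoid_r2 <- function(dm, spacing, centre, radii) {
  cs <- grid_coords(dm, spacing)
  x2 <- ((cs[[1]] - centre[1]) / radii[1])^2
  y2 <- ((cs[[2]] - centre[2]) / radii[2])^2
  z2 <- ((cs[[3]] - centre[3]) / radii[3])^2
  outer(outer(x2, y2, `+`), z2, `+`)
}

standardised_field <- function(dm, sigma_vox = 1.5) {
  f <- smooth_gaussian3(array(stats::rnorm(prod(dm)), dm), sigma_vox)
  (f - mean(f)) / stats::sd(f)
}

#' Simulate one phantom PET/CT lesion
#'
#' Builds an ellipsoidal lesion with a smooth radial uptake profile
#' (amplitude at the centre, 41% of amplitude at the drawn radius, truncated
#' at twice the radius), an optional multiplicative correlated log-normal
#' texture field scaled by the cluster heterogeneity weight, an optional
#' necrotic core, additive Gaussian PET noise (clipped at 0), and a paired
#' CT volume with lesion HU contrast and matching texture. Deterministic
#' given `seed`.
#'
#' @param cluster `"cluster1"`, `"cluster2"` or `"sporadic"`.
#' @param params a [cluster_sim_params()] list.
#' @param seed integer seed.
#' @return A list of class `synthetic_lesion`: `pet`, `ct` (NULL when
#'   `params$simulate_ct` is FALSE), `truth_mask`, `cluster`, `biochemistry`,
#'   `true_diameter` (equivalent-sphere, mm), `true_suvmax`, `draw`.
#' @export
simulate_lesion <- function(cluster, params = cluster_sim_params(), seed = 1L) {
  cluster <- match.arg(cluster, valid_clusters)
  with_seed(seed, {
    dr <- draw_lesion_params(cluster, params)
    dm <- params$pet_dim; sp <- params$pet_spacing
    jitter <- stats::runif(3, -0.5, 0.5) * sp
    dr$jitter <- jitter
    r2 <- ellipsoid_r2(dm, sp, jitter, dr$radii)
    sig2 <- params$profile_sigma^2
    g <- exp(-r2 / (2 * sig2))
    g[r2 > 4] <- 0                     # truncate support at twice the radius
    bg <- params$background_suv
    lesion <- (dr$amplitude - bg) * g
    if (dr$necrotic)
      lesion <- lesion * (1 - params$necrosis_depth * exp(-r2 / (2 * 0.35^2)))
    if (dr$heterogeneity > 0) {
      tau <- params$texture_logsd * dr$heterogeneity
      f <- standardised_field(dm)
      lesion <- lesion * exp(tau * f - tau^2 / 2)
    }
    pet_data <- bg + lesion
    if (isTRUE(params$distractor)) {
      d2 <- ellipsoid_r2(dm, sp, params$distractor_offset_mm,
                         rep(params$distractor_radius_mm, 3))
      pet_data <- pet_data +
        (params$distractor_amplitude - bg) * exp(-d2 / (2 * sig2)) *
        (d2 <= 4)
    }
    if (params$pet_noise_sd > 0)
      pet_data <- pet_data + stats::rnorm(length(pet_data), 0,
                                          params$pet_noise_sd)
    pet_data <- pmax(array(pet_data, dm), 0)
    pet_origin <- -(dm - 1) / 2 * sp
    pet <- image_volume(pet_data, sp, pet_origin)
    truth <- voi_mask(r2 <= 1, sp, pet_origin)

    ct <- NULL
    if (isTRUE(params$simulate_ct)) {
      cdm <- params$ct_dim; csp <- params$ct_spacing
      cr2 <- ellipsoid_r2(cdm, csp, jitter, dr$radii)
      hu <- array(stats::rnorm(prod(cdm), params$ct_background_hu_mean,
                               params$ct_background_hu_sd), cdm)
      inside <- cr2 <= 1
      n_in <- sum(inside)
      if (n_in > 0) {
        # correlated texture only needs the lesion bounding box
        cc <- coord_from_lin(which(inside), cdm)
        lo <- pmax(apply(cc, 2, min) - 3L, 1L)
        hi <- pmin(apply(cc, 2, max) + 3L, cdm)
        fct <- array(0, cdm)
        fct[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          standardised_field(hi - lo + 1L)
        hu[inside] <- stats::rnorm(n_in, params$ct_lesion_hu_mean,
                                   params$ct_lesion_hu_sd) +
          dr$heterogeneity * params$ct_texture_scale * fct[inside]
      }
      ct <- image_volume(hu, csp, -(cdm - 1) / 2 * csp)
    }
    bio <- simulate_biochemistry(cluster, params,
                                 seed = derive_seed(seed, 104729L))
    structure(list(
      pet = pet, ct = ct, truth_mask = truth, cluster = cluster,
      biochemistry = bio,
      true_diameter = 2 * prod(dr$radii)^(1 / 3),
      true_suvmax = max(pet_data[truth$data]),
      draw = dr
    ), class = "synthetic_lesion")
  })
}

#' Simulate the dichotomous biochemical profile of a lesion
#'
#' Three independent Bernoulli draws (adrenergic, noradrenergic,
#' dopaminergic); combinations are allowed. Cluster-specific probabilities
#' come from `params` (cluster 1 noradrenergic/dopaminergic-dominant,
#' cluster 2 adrenergic-dominant).
#'
#' @inheritParams simulate_lesion
#' @return Named logical vector of length 3.
#' @export
simulate_biochemistry <- function(cluster, params = cluster_sim_params(),
                                  seed = 1L) {
  cluster <- match.arg(cluster, valid_clusters)
  pr <- if (cluster == "sporadic") params$sporadic_biochem
  else params$clusters[[cluster]]$biochem
  stopifnot(all(pr >= 0 & pr <= 1))
  with_seed(seed, {
    out <- stats::runif(3) < pr
    names(out) <- c("adrenergic", "noradrenergic", "dopaminergic")
    out
  })
}

#' Simulate a lesion cohort
#'
#' @param n1,n2,ns numbers of cluster-1, cluster-2 and sporadic lesions
#'   (defaults 13, 18, 9 -- the clinical design).
#' @param params a [cluster_sim_params()] list.
#' @param seed master seed; per-lesion seeds are derived by a counter-based
#'   scheme, so extending a cohort does not reshuffle existing lesions.
#' @return List of class `synthetic_cohort` of [simulate_lesion()] objects.
#' @export
simulate_cohort <- function(n1 = 13L, n2 = 18L, ns = 9L,
                            params = cluster_sim_params(), seed = 1L) {
  stopifnot(n1 >= 0, n2 >= 0, ns >= 0)
  if (n1 + n2 + ns == 0) stop("cohort must contain at least one lesion")
  labels <- c(rep("cluster1", n1), rep("cluster2", n2), rep("sporadic", ns))
  out <- vector("list", length(labels))
  for (i in seq_along(labels))
    out[[i]] <- simulate_lesion(labels[i], params, seed = derive_seed(seed, i))
  structure(out, class = c("synthetic_cohort", "list"))
}

#' Cohort metadata table
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame with id, cluster, biochemistry flags and ground truth.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    id = sprintf("lesion%03d", seq_along(cohort)),
    cluster = vapply(cohort, `[[`, "", "cluster"),
    adrenergic = vapply(cohort, function(l) l$biochemistry[["adrenergic"]],
                        FALSE),
    noradrenergic = vapply(cohort,
                           function(l) l$biochemistry[["noradrenergic"]],
                           FALSE),
    dopaminergic = vapply(cohort,
                          function(l) l$biochemistry[["dopaminergic"]],
                          FALSE),
    true_suvmax = vapply(cohort, `[[`, 0, "true_suvmax"),
    true_diameter = vapply(cohort, `[[`, 0, "true_diameter"),
    stringsAsFactors = FALSE
  )
}
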