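# Feature registry and per-lesion / per-cohort extraction.

#' Radiomic feature registry
#'
#' Names and family composition of the per-modality 105-feature set:
#' 18 first-order + 14 shape + 73 texture (22 GLCM + 16 GLRLM + 16 GLSZM +
#' 5 NGTDM + 14 GLDM). Of the 24 named co-occurrence features, SumAverage
#' (identically twice JointAverage for symmetric matrices) and the
#' eigen-based maximal correlation coefficient are excluded; the registry is
#' the single source of truth for names and counts.
#'
#' @return Named list of character vectors, one per family.
#' @export
feature_registry <- function() {
  list(
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "10Percentile", "90Percentile", "Maximum", "Mean",
                   "Median", "InterquartileRange", "Range",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                   "Uniformity"),
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea",
              "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
              "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation", "Flatness"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy",
             "MaximumProbability", "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "RunPercentage", "GrayLevelVariance", "RunVariance",
              "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
              "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity",
              "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis")
  )
}

#' Names of the per-modality feature columns
#'
#' `modality_family_feature`, e.g. `PET_firstorder_Entropy`.
#' @param modality "PET" or "CT".
#' @return Character vector of 105 names.
#' @export
modality_feature_names <- function(modality) {
  reg <- feature_registry()
  unlist(lapply(names(reg), function(fam)
    paste(modality, fam, reg[[fam]], sep = "_")), use.names = FALSE)
}

#' Total lesion glycolysis
#'
#' The product of the mean SUV and the metabolic tumour volume.
#' @param suv_mean mean SUV inside the VOI (g/mL).
#' @param mtv_cm3 metabolic tumour volume (cm^3).
#' @return TLG in grams.
#' @export
tlg <- function(suv_mean, mtv_cm3) suv_mean * mtv_cm3

extract_modality <- function(volume, mask, bin_width) {
  reg <- feature_registry()
  disc <- discretise(volume, mask, bin_width)
  fams <- list(firstorder = first_order_features(disc),
               shape = shape_features(mask),
               glcm = glcm_features(disc),
               glrlm = glrlm_features(disc),
               glszm = glszm_features(disc),
               ngtdm = ngtdm_features(disc),
               gldm = gldm_features(disc))
  for (fam in names(reg)) {
    if (!identical(names(fams[[fam]]), reg[[fam]]))
      stop("feature registry mismatch in ", fam, ": ",
           paste(setdiff(reg[[fam]], names(fams[[fam]])), collapse = ", "))
  }
  out <- unlist(unname(fams))
  names(out) <- unlist(lapply(names(reg), function(fam)
    paste(fam, reg[[fam]], sep = "_")), use.names = FALSE)
  out
}

#' Extract the full 211-feature block for one lesion
#'
#' 105 PET features on the native PET grid with the PET VOI, 105 CT
#' features on the 1.5 mm isotropic resampled CT with the (resampled) CT
#' VOI, plus TLG = SUVmean x MTV (MTV = PET mesh volume in cm^3).
#'
#' @param pet PET [image_volume()] (SUV).
#' @param pet_mask PET [voi_mask()].
#' @param ct CT [image_volume()] (HU), or NULL to skip the CT block.
#' @param ct_mask CT [voi_mask()] on the CT grid.
#' @param config a [radiomics_config()].
#' @return Named numeric vector: 105 PET (+ 105 CT when CT given) + TLG.
#' @export
extract_lesion <- function(pet, pet_mask, ct = NULL, ct_mask = NULL,
                           config = radiomics_config()) {
  pet_f <- extract_modality(pet, pet_mask, config$pet_bin_width)
  names(pet_f) <- paste0("PET_", names(pet_f))
  out <- pet_f
  if (!is.null(ct)) {
    stopifnot(!is.null(ct_mask))
    rs <- resample_isotropic(ct, config, mask = ct_mask)
    ct_f <- extract_modality(rs$volume, rs$mask, config$ct_bin_width)
    names(ct_f) <- paste0("CT_", names(ct_f))
    out <- c(out, ct_f)
  }
  mtv_cm3 <- pet_f[["PET_shape_MeshVolume"]] / 1000
  c(out, TLG = tlg(pet_f[["PET_firstorder_Mean"]], mtv_cm3))
}

# CT-grid truth mask of a synthetic lesion, rebuilt from the stored draw.
lesion_ct_mask <- function(lesion) {
  stopifnot(inherits(lesion, "synthetic_lesion"), !is.null(lesion$ct))
  cdm <- dim(lesion$ct$data)
  r2 <- ellipsoid_r2(cdm, lesion$ct$spacing, lesion$draw$jitter,
                     lesion$draw$radii)
  voi_mask(r2 <= 1, lesion$ct$spacing, lesion$ct$origin)
}

#' Segment and extract features for a whole synthetic cohort
#'
#' PET VOIs come from the background-corrected adaptive isocontour; CT VOIs
#' are the ground-truth ellipsoid masks on the CT grid (the clinical
#' workflow delineates CT manually, so CT masks are externally supplied).
#' Lesions whose PET VOI fails the 64-voxel size filter are excluded from
#' the returned table and listed in `attr(, "excluded")`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config a [radiomics_config()].
#' @param modalities `c("PET", "CT")` or `"PET"` for a PET-only table.
#' @param verbose print progress.
#' @return data.frame: id, cluster, biochemistry flags, then the feature
#'   columns (211, or 106 for PET-only).
#' @export
extract_cohort <- function(cohort, config = radiomics_config(),
                           modalities = c("PET", "CT"), verbose = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  use_ct <- "CT" %in% modalities
  meta <- cohort_table(cohort)
  rows <- vector("list", length(cohort))
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    les <- cohort[[i]]
    seg <- segment_pet(les$pet)
    if (!seg$passed_size_filter) {
      excluded <- c(excluded, meta$id[i])
      next
    }
    ct <- NULL; ctm <- NULL
    if (use_ct) {
      if (is.null(les$ct))
        stop("cohort was simulated without CT but CT features requested")
      ct <- les$ct
      ctm <- lesion_ct_mask(les)
    }
    feats <- extract_lesion(les$pet, seg$mask, ct, ctm, config)
    rows[[i]] <- data.frame(meta[i, c("id", "cluster", "adrenergic",
                                      "noradrenergic", "dopaminergic")],
                            as.list(feats), check.names = FALSE)
    if (verbose)
      message(sprintf("extracted %s (%s): %d features", meta$id[i],
                      meta$cluster[i], length(feats)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
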