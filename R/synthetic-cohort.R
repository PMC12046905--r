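#' Specification of a three-zone tumor phantom
#'
#' Describes the synthetic stand-in for a venous-phase CT tumor: an ellipsoid
#' painted as three concentric intensity zones -- a dark necrotic core, an
#' intermediate transition shell and a bright enhancing rim -- over a noisy
#' background, with Gaussian noise and smoothing applied after painting.
#' Zone boundaries are placed so the painted voxel proportions match
#' `zoneFractions` (equal-volume shells of the ellipsoid).
#'
#' @param gridShape integer(3) voxels per axis.
#' @param spacingMm numeric(3) voxel size in mm.
#' @param tumorRadiusMm numeric(3) ellipsoid semi-axes in mm.
#' @param zoneFractions proportions of necrotic / transition / enhancing
#'   voxels; must be non-negative and sum to 1.
#' @param zoneMeans mean intensity per zone (HU-like units), darkest first.
#' @param zoneSds intensity noise SD per zone (marginal SD, after any
#'   texture-grain correlation).
#' @param textureGrainMm spatial correlation length of each zone's noise
#'   texture (0 = white noise).  Necrotic fluid is fine-grained and
#'   homogeneous while the vascularised enhancing rim shows coarse
#'   heterogeneity, so the grain grows from core to rim by default; this is
#'   what makes the zones distinct *texture* habitats rather than mere
#'   intensity bands.
#' @param smoothingSigmaMm Gaussian blur applied after painting (0 = none).
#' @param backgroundMean,backgroundSd surrounding-tissue intensity model.
#' @param enhancingBoost added to the enhancing fraction for node-positive
#'   phantoms (other zones rescaled), the imaging effect that links
#'   morphology to the outcome label.
#' @return A `PhantomSpec` list.
#' @seealso [generatePhantom()], [generateCohort()]
#' @export
phantomSpec <- function(gridShape = c(36, 36, 36), spacingMm = c(1, 1, 1),
                        tumorRadiusMm = c(10, 10, 10),
                        zoneFractions = c(necrotic = 0.20, transition = 0.30,
                                          enhancing = 0.50),
                        zoneMeans = c(25, 60, 90), zoneSds = c(10, 10, 10),
                        textureGrainMm = c(0, 0.75, 1.5),
                        smoothingSigmaMm = 0, backgroundMean = 0,
                        backgroundSd = 10, enhancingBoost = 0.08) {
    spec <- list(gridShape = as.integer(gridShape),
                 spacingMm = as.numeric(spacingMm),
                 tumorRadiusMm = as.numeric(tumorRadiusMm),
                 zoneFractions = as.numeric(zoneFractions),
                 zoneMeans = as.numeric(zoneMeans),
                 zoneSds = as.numeric(zoneSds),
                 textureGrainMm = as.numeric(textureGrainMm),
                 smoothingSigmaMm = smoothingSigmaMm,
                 backgroundMean = backgroundMean,
                 backgroundSd = backgroundSd,
                 enhancingBoost = enhancingBoost)
    class(spec) <- "PhantomSpec"
    validatePhantomSpec(spec)
    spec
}

validatePhantomSpec <- function(spec) {
    f <- spec$zoneFractions
    if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
        stop("zoneFractions must be 3 non-negative values summing to 1")
    if (any(spec$spacingMm <= 0)) stop("spacingMm must be positive")
    radVox <- ceiling(spec$tumorRadiusMm / spec$spacingMm)
    if (any(2 * (radVox + 2) > spec$gridShape))
        stop("tumor does not fit in the grid with a 2-voxel margin")
    invisible(TRUE)
}

# per-patient zone fractions with the node-positive enhancing boost
boostFractions <- function(f, boost) {
    fe <- min(f[3] + boost, 0.95)
    rest <- 1 - fe
    f12 <- if (sum(f[1:2]) > 0) f[1:2] * rest / sum(f[1:2]) else c(rest / 2,
                                                                   rest / 2)
    c(f12, fe)
}

#' Generate a three-zone tumor phantom
#'
#' Paints an ellipsoid tumor with concentric necrotic / transition /
#' enhancing zones into a noisy background, adds per-zone Gaussian noise and
#' an optional Gaussian blur.  Node-positive phantoms receive a larger
#' enhancing fraction (`spec$enhancingBoost`).
#'
#' @param spec a [phantomSpec()].
#' @param pnLabel 0/1 pathological node label driving the enhancing boost.
#' @param seed integer; fully determines the output.
#' @param zoneFractions optional per-call override of the painted fractions
#'   (used by [generateCohort()], which draws patient-level fractions).
#' @return A list of class `SyntheticPatient` with elements `image`
#'   ([ImageVolume-class]), `mask` (binary [MaskVolume-class]), `zones`
#'   (ground-truth zone labels 1 = necrotic, 2 = transition, 3 = enhancing),
#'   `zoneFractions` and `pnLabel`.
#' @examples
#' p <- generatePhantom(phantomSpec(gridShape = c(24, 24, 24),
#'                                  tumorRadiusMm = c(7, 7, 7)), seed = 1)
#' p$mask
#' @export
generatePhantom <- function(spec, pnLabel = 0, seed = 1,
                            zoneFractions = NULL) {
    validatePhantomSpec(spec)
    d <- spec$gridShape
    sp <- spec$spacingMm
    f <- if (!is.null(zoneFractions)) zoneFractions else spec$zoneFractions
    if (pnLabel > 0 && is.null(zoneFractions))
        f <- boostFractions(f, spec$enhancingBoost)
    ctr <- (d - 1) / 2
    ax <- (seq_len(d[1]) - 1 - ctr[1]) * sp[1] / spec$tumorRadiusMm[1]
    ay <- (seq_len(d[2]) - 1 - ctr[2]) * sp[2] / spec$tumorRadiusMm[2]
    az <- (seq_len(d[3]) - 1 - ctr[3]) * sp[3] / spec$tumorRadiusMm[3]
    rho2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
    inside <- rho2 <= 1
    if (!any(inside)) stop("tumor radius too small for this grid")
    # equal-volume concentric shells: fraction within normalized radius r is r^3
    r1 <- f[1]^(1 / 3)
    r2 <- (f[1] + f[2])^(1 / 3)
    zones <- array(0L, d)
    zones[inside] <- 3L
    zones[inside & rho2 <= r2^2] <- 2L
    zones[inside & rho2 <= r1^2] <- 1L
    withSeed(seed, {
        noise <- array(rnorm(prod(d)), d)
        # per-zone texture: correlated noise fields with unit marginal SD
        fields <- lapply(spec$textureGrainMm, function(g) {
            if (g <= 0) return(noise)
            f <- gaussSmooth(noise, g / sp)
            f / sd(as.vector(f))
        })
        img <- array(spec$backgroundMean, d) + noise * spec$backgroundSd
        for (z in 1:3) {
            sel <- zones == z
            img[sel] <- spec$zoneMeans[z] + fields[[z]][sel] * spec$zoneSds[z]
        }
    })
    if (spec$smoothingSigmaMm > 0)
        img <- gaussSmooth(img, spec$smoothingSigmaMm / sp)
    out <- list(image = imageVolume(img, spacing = sp),
                mask = maskVolume(array(as.integer(inside), d), spacing = sp),
                zones = maskVolume(zones, spacing = sp),
                zoneFractions = f, pnLabel = pnLabel)
    class(out) <- "SyntheticPatient"
    out
}

#' Randomly perturb a mask boundary
#'
#' Emulates inter-/intra-observer segmentation variability by displacing the
#' mask surface with a smooth band-limited random field: a blurred white-noise
#' field, standardised and clamped to `[-1, 1]`, moves the boundary along the
#' signed distance by at most `magnitudeMm`.  The perturbed mask therefore
#' always stays within `magnitudeMm` of the original surface.
#'
#' @param mask nonempty binary [MaskVolume-class].
#' @param magnitudeMm maximal physical boundary displacement (mm); 0 returns
#'   the mask unchanged.
#' @param seed integer seed.
#' @param correlationMm spatial correlation length of the displacement field.
#' @return A perturbed [MaskVolume-class].
#' @export
perturbMask <- function(mask, magnitudeMm, seed = 1, correlationMm = 3) {
    fg <- mask@values > 0
    if (!any(fg)) stop("mask is empty")
    if (magnitudeMm == 0) return(mask)
    if (magnitudeMm < 0) stop("magnitudeMm must be non-negative")
    d <- dim(mask@values)
    sp <- mask@spacing
    cap <- magnitudeMm + max(sp)
    dOut <- cpp_capped_distance(as.logical(fg), d, sp, cap)
    dIn <- cpp_capped_distance(as.logical(!fg), d, sp, cap)
    sdist <- array(ifelse(fg, -dIn, dOut), d)  # negative inside
    field <- withSeed(seed, array(rnorm(prod(d)), d))
    field <- gaussSmooth(field, correlationMm / sp)
    field <- field / sd(as.vector(field))
    field <- pmin(1, pmax(-1, field))
    newfg <- sdist <= field * magnitudeMm
    if (!any(newfg))
        stop("perturbation magnitude removes the entire mask")
    maskVolume(array(as.integer(newfg), d), spacing = sp,
               origin = mask@origin)
}

#' Specification of a synthetic patient cohort
#'
#' Parameters of the clinical-covariate, outcome-label and survival models
#' used by [generateCohort()].  Covariate marginals default to values typical
#' of a cN0 head-and-neck squamous cell carcinoma cohort (predominantly male
#' smokers, occult-metastasis prevalence around 30%).  The node label is
#' drawn from a logistic model whose linear predictor combines clinical
#' covariates, radiologic features and the phantom's enhancing-zone fraction;
#' the intercept is calibrated so the expected prevalence matches
#' `prevalence`.  Survival is exponential with a proportional hazard for
#' node-positive patients and uniform administrative censoring.
#'
#' @param nPatients number of patients (>= 2).
#' @param prevalence target node-positive fraction, in (0, 1).
#' @param covariateModel list of marginals: `sexMale`, `smoking`, `alcohol`
#'   Bernoulli probabilities; `gradeProbs`, `tStageProbs` category
#'   probabilities; `ageMean`, `ageSd`.
#' @param effectSizes named log-odds effects on the node label:
#'   `tStage` (per stage above T1), `gradePoor`, `diameterCm` (per cm above
#'   average), `enhancingFraction` (per unit fraction above average),
#'   `necrosis`, `heterogeneous`.
#' @param survivalModel list: `baselineHazardDfs`, `baselineHazardOs`
#'   (events/month for node-negative patients), `hazardRatio` (node-positive
#'   vs negative), `censorMinMonths`, `censorMaxMonths` (administrative
#'   censoring window).
#' @param interObserverMm,intraObserverMm boundary perturbation amplitudes
#'   for the duplicate observer masks.
#' @param seed integer; fully determines the cohort.
#' @return A `CohortSpec` list.
#' @export
cohortSpec <- function(nPatients = 100, prevalence = 0.30,
                       covariateModel = list(sexMale = 0.96, smoking = 0.92,
                                             alcohol = 0.70,
                                             gradeProbs = c(Poor = 0.18,
                                                            Moderate = 0.47,
                                                            Well = 0.35),
                                             tStageProbs = c(T1 = 0.27,
                                                             T2 = 0.34,
                                                             T3 = 0.28,
                                                             T4 = 0.11),
                                             ageMean = 62, ageSd = 8.6),
                       effectSizes = c(tStage = 0.55, gradePoor = 0.8,
                                       diameterCm = 0.9,
                                       enhancingFraction = 5,
                                       necrosis = 0.6, heterogeneous = 0.5),
                       survivalModel = list(baselineHazardDfs = 0.015,
                                            baselineHazardOs = 0.010,
                                            hazardRatio = 2.5,
                                            censorMinMonths = 12,
                                            censorMaxMonths = 60),
                       interObserverMm = 1.0, intraObserverMm = 0.5,
                       seed = 1) {
    if (prevalence <= 0 || prevalence >= 1)
        stop("prevalence must lie strictly between 0 and 1")
    if (nPatients < 2) stop("nPatients must be at least 2")
    spec <- list(nPatients = as.integer(nPatients), prevalence = prevalence,
                 covariateModel = covariateModel, effectSizes = effectSizes,
                 survivalModel = survivalModel,
                 interObserverMm = interObserverMm,
                 intraObserverMm = intraObserverMm, seed = as.integer(seed))
    class(spec) <- "CohortSpec"
    spec
}

#' Generate a synthetic patient cohort
#'
#' Draws clinical covariates, patient-level tumor geometry and zone
#' fractions, node labels from the logistic outcome model, exponential
#' survival with administrative censoring, and (optionally) the phantom
#' image, tumor mask, ground-truth zone map and two perturbed observer masks
#' for every patient.
#'
#' @param spec a [cohortSpec()].
#' @param phantom a [phantomSpec()] describing the imaging model.
#' @param images logical; when `FALSE` only the clinical table is generated
#'   (fast path for statistical calibration work).
#' @return A list of class `SyntheticCohort` with elements `clinical` (one
#'   row per patient: id, age, sex, smoking, alcohol, grade, tStage,
#'   tumorVolumeCm3, maxDiameterCm, heterogeneous, necrosis, zone fractions,
#'   `pn` 0/1, `dfsMonths`/`dfsEvent`, `osMonths`/`osEvent`) and `patients`
#'   (per-patient list with `image`, `mask`, `zones`, `maskObserver2`,
#'   `maskRepeat`; `NULL` rows when `images = FALSE`).
#' @examples
#' coh <- generateCohort(cohortSpec(nPatients = 50, seed = 7), images = FALSE)
#' mean(coh$clinical$pn)
#' @export
generateCohort <- function(spec, phantom = phantomSpec(), images = TRUE) {
    n <- spec$nPatients
    cm <- spec$covariateModel
    ef <- spec$effectSizes
    withSeed(spec$seed, {
        age <- rnorm(n, cm$ageMean, cm$ageSd)
        sex <- rbinom(n, 1, cm$sexMale)            # 1 = male
        smoking <- rbinom(n, 1, cm$smoking)
        alcohol <- rbinom(n, 1, cm$alcohol)
        grade <- factor(names(cm$gradeProbs)[apply(
            rmultinom(n, 1, cm$gradeProbs), 2, which.max)],
            levels = names(cm$gradeProbs))
        tStage <- factor(names(cm$tStageProbs)[apply(
            rmultinom(n, 1, cm$tStageProbs), 2, which.max)],
            levels = names(cm$tStageProbs))
        radScale <- exp(rnorm(n, 0, 0.2))          # patient size factor
        radii <- outer(radScale, phantom$tumorRadiusMm)
        diameterCm <- 2 * apply(radii, 1, max) / 10
        volumeCm3 <- 4 / 3 * pi * apply(radii, 1, prod) / 1000
        # patient-level zone fractions: logit-jitter around the spec values
        base <- phantom$zoneFractions
        jit <- matrix(rnorm(3 * n, 0, 0.3), n, 3)
        raw <- sweep(exp(jit), 2, base, `*`)
        fractions <- raw / rowSums(raw)
        colnames(fractions) <- c("necrotic", "transition", "enhancing")
        necrosis <- rbinom(n, 1, plogis(qlogis(0.16) +
                                        6 * (fractions[, 1] - base[1])))
        heterogeneous <- rbinom(n, 1, plogis(qlogis(0.28) +
                                             4 * (1 - fractions[, 3] -
                                                  (1 - base[3]))))
        eta <- ef["tStage"] * (as.integer(tStage) - 1) +
            ef["gradePoor"] * (grade == "Poor") +
            ef["diameterCm"] * (diameterCm - mean(diameterCm)) +
            ef["enhancingFraction"] * (fractions[, 3] - mean(fractions[, 3])) +
            ef["necrosis"] * necrosis + ef["heterogeneous"] * heterogeneous
        intercept <- uniroot(function(b) mean(plogis(b + eta)) -
                                 spec$prevalence, c(-30, 30))$root
        pn <- rbinom(n, 1, plogis(intercept + eta))
        sv <- spec$survivalModel
        hr <- sv$hazardRatio^pn
        dfsT <- rexp(n, sv$baselineHazardDfs * hr)
        osT <- pmax(dfsT, rexp(n, sv$baselineHazardOs * hr))
        cens <- runif(n, sv$censorMinMonths, sv$censorMaxMonths)
    })
    clinical <- data.frame(
        id = sprintf("P%03d", seq_len(n)), age = age, sex = sex,
        smoking = smoking, alcohol = alcohol, grade = grade, tStage = tStage,
        tumorVolumeCm3 = volumeCm3, maxDiameterCm = diameterCm,
        heterogeneous = heterogeneous, necrosis = necrosis,
        necroticFraction = fractions[, 1],
        transitionFraction = fractions[, 2],
        enhancingFraction = fractions[, 3], pn = pn,
        dfsMonths = pmin(dfsT, cens), dfsEvent = as.integer(dfsT <= cens),
        osMonths = pmin(osT, cens), osEvent = as.integer(osT <= cens),
        stringsAsFactors = FALSE)
    patients <- vector("list", n)
    if (images) {
        for (i in seq_len(n)) {
            ps <- phantom
            ps$tumorRadiusMm <- pmin(phantom$tumorRadiusMm * radScale[i],
                                     (phantom$gridShape / 2 - 3) *
                                         phantom$spacingMm)
            pat <- generatePhantom(ps, pnLabel = pn[i],
                                   seed = deriveSeed(spec$seed, i),
                                   zoneFractions = fractions[i, ])
            pat$maskObserver2 <- perturbMask(pat$mask, spec$interObserverMm,
                                             seed = deriveSeed(spec$seed,
                                                               i + 10000L))
            pat$maskRepeat <- perturbMask(pat$mask, spec$intraObserverMm,
                                          seed = deriveSeed(spec$seed,
                                                            i + 20000L))
            patients[[i]] <- pat
        }
    }
    out <- list(clinical = clinical, patients = patients, spec = spec,
                phantom = phantom)
    class(out) <- "SyntheticCohort"
    out
}

#' Simulate a ready-made feature table with known informative features
#'
#' A cohort-level feature matrix for selection and classifier studies:
#' `nInformative` features carry a class-conditional mean shift sized so the
#' Bayes-optimal AUC of the generator equals `bayesAuc`; the remaining
#' `nNoise` features are independent standard normal.
#'
#' @param n patients.
#' @param nInformative,nNoise feature counts.
#' @param bayesAuc Bayes-optimal AUC of the generating model.
#' @param prevalence positive-class fraction.
#' @param seed integer seed.
#' @return list with `table` (data.frame, columns `inf_*` then `noise_*`),
#'   `labels` (0/1) and `delta` (the per-feature mean shift).
#' @export
simulateFeatureTable <- function(n = 300, nInformative = 3, nNoise = 47,
                                 bayesAuc = 0.90, prevalence = 0.5,
                                 seed = 1) {
    delta <- qnorm(bayesAuc) * sqrt(2) / sqrt(nInformative)
    withSeed(seed, {
        labels <- rbinom(n, 1, prevalence)
        X <- matrix(rnorm(n * (nInformative + nNoise)), n)
        X[, seq_len(nInformative)] <- X[, seq_len(nInformative)] +
            (labels - 0.5) * delta
    })
    colnames(X) <- c(sprintf("inf_%d", seq_len(nInformative)),
                     sprintf("noise_%d", seq_len(nNoise)))
    list(table = as.data.frame(X), labels = labels, delta = delta)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-patient NIfTI volumes (`<id>_image.nii.gz`, `<id>_mask.nii.gz`,
#' observer replicates, ground-truth zones) plus `clinical.csv` and a JSON
#' column dictionary.
#'
#' @param cohort a [generateCohort()] result with images.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cl <- cohort$clinical
    write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
    dict <- list(
        id = "patient identifier",
        age = "age in years", sex = "1 = male, 0 = female",
        smoking = "1 = smoker", alcohol = "1 = alcohol consumption",
        grade = "histological grade (Poor/Moderate/Well)",
        tStage = "clinical T stage (T1..T4)",
        tumorVolumeCm3 = "radiologic tumor volume (cm^3)",
        maxDiameterCm = "radiologic maximum tumor diameter (cm)",
        heterogeneous = "1 = heterogeneous enhancement pattern",
        necrosis = "1 = intratumoral necrosis",
        pn = "pathological node status (1 = pN+)",
        dfsMonths = "disease-free survival time (months)",
        dfsEvent = "1 = DFS event observed, 0 = censored",
        osMonths = "overall survival time (months)",
        osEvent = "1 = OS event observed, 0 = censored")
    jsonlite::write_json(dict, file.path(dir, "clinical_dictionary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (i in seq_along(cohort$patients)) {
        pat <- cohort$patients[[i]]
        if (is.null(pat)) next
        id <- cl$id[i]
        writeVolume(pat$image, file.path(dir, paste0(id, "_image.nii.gz")))
        writeVolume(pat$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
        writeVolume(pat$zones, file.path(dir, paste0(id, "_zones.nii.gz")))
        writeVolume(pat$maskObserver2,
                    file.path(dir, paste0(id, "_mask_observer2.nii.gz")))
        writeVolume(pat$maskRepeat,
                    file.path(dir, paste0(id, "_mask_repeat.nii.gz")))
    }
    invisible(dir)
}
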