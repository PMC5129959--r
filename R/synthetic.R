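#' Configuration of a synthetic spread-type cohort
#'
#' Collects the design parameters of a simulated cohort: patient numbers, the
#' miliary fraction, tissue origins sampled per patient (P primary ovarian, M
#' peritoneal metastasis, A ascitic single cells, S ascitic spheroids),
#' feature counts per biotype, the negative-binomial dispersion, and
#' sequencing depth. Defaults mirror the study design the package models: 23
#' patients (11 miliary, 12 non-miliary), four tissue origins each, and a
#' median library of about 14.2 million reads.
#'
#' @param nPatients Number of patients.
#' @param spreadFraction Fraction of patients with miliary spread.
#' @param tissueOrigins Subset of \code{c("P","M","A","S")}.
#' @param nCoding,nLncRNA,nMiRNA,nPiRNA,nSnRNA,nSnoRNA Feature counts per
#'   biotype.
#' @param nbDispersion Negative-binomial dispersion (variance =
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson counts.
#' @param libSizeMean Expected total reads per sample.
#' @param libSizeSpread Log-normal sdlog of per-sample library-size factors.
#' @param patientSd Between-patient biological sd on the log2 scale; drawn
#'   per patient and feature, shared by all of that patient's samples (ascitic
#'   and solid), inducing the within-patient correlation of repeated
#'   measurements.
#' @param nUpMiRNAs Number of miRNAs designated miliary-up regulators whose
#'   targets carry the planted suppression.
#' @param meanTargetsPerMiRNA Mean number of coding targets per miRNA in the
#'   generated interaction table.
#' @param nGeneSets,setSizeRange,plantedSetFraction Gene-set collection size,
#'   member-count range, and the fraction of sets built around targets of the
#'   up-miRNAs (carrying the planted set-level signal).
#' @param backSpliceRate Baseline back-splice fraction of all splice events.
#' @param junctionDepth Expected total splice-junction events per sample.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   cohorts.
#'
#' @return A validated list of class \code{"CohortConfig"}.
#' @seealso \code{\link{generateCohort}}, \code{\link{plantedEffects}}
#' @export
#' @examples
#' cohortConfig(nPatients = 8, nCoding = 100)
cohortConfig <- function(nPatients = 23, spreadFraction = 11 / 23,
                         tissueOrigins = c("P", "M", "A", "S"),
                         nCoding = 2000, nLncRNA = 600, nMiRNA = 800,
                         nPiRNA = 300, nSnRNA = 60, nSnoRNA = 80,
                         nbDispersion = 0.2, libSizeMean = 14.2e6,
                         libSizeSpread = 0.25, patientSd = 0.25,
                         nUpMiRNAs = 20, meanTargetsPerMiRNA = 30,
                         nGeneSets = 200, setSizeRange = c(15, 40),
                         plantedSetFraction = 0.25,
                         backSpliceRate = 0.1, junctionDepth = 2e5,
                         seed = 1L) {
  cfg <- list(nPatients = nPatients, spreadFraction = spreadFraction,
              tissueOrigins = match.arg(tissueOrigins,
                                        c("P", "M", "A", "S"),
                                        several.ok = TRUE),
              nCoding = nCoding, nLncRNA = nLncRNA, nMiRNA = nMiRNA,
              nPiRNA = nPiRNA, nSnRNA = nSnRNA, nSnoRNA = nSnoRNA,
              nbDispersion = nbDispersion, libSizeMean = libSizeMean,
              libSizeSpread = libSizeSpread, patientSd = patientSd,
              nUpMiRNAs = nUpMiRNAs,
              meanTargetsPerMiRNA = meanTargetsPerMiRNA,
              nGeneSets = nGeneSets, setSizeRange = setSizeRange,
              plantedSetFraction = plantedSetFraction,
              backSpliceRate = backSpliceRate,
              junctionDepth = junctionDepth, seed = as.integer(seed))
  stopifnot(cfg$nPatients >= 1,
            cfg$spreadFraction >= 0, cfg$spreadFraction <= 1,
            cfg$nCoding >= 0, cfg$nLncRNA >= 0, cfg$nMiRNA >= 0,
            cfg$nPiRNA >= 0, cfg$nSnRNA >= 0, cfg$nSnoRNA >= 0,
            cfg$nbDispersion >= 0, cfg$libSizeMean > 0,
            cfg$backSpliceRate > 0, cfg$backSpliceRate < 1)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Planted effect sizes for synthetic cohorts
#'
#' Effect magnitudes planted into a generated cohort. Setting every effect to
#' zero yields null data with no spread-type structure. Defaults reproduce
#' the qualitative pattern the analysis targets: globally reduced lncRNA
#' abundance and back-splice index in miliary solid samples with unchanged
#' miRNA totals, suppressed targets of designated up-miRNAs, a planted
#' spread signature, and survival effects equal to the published
#' training-cohort Cox coefficients.
#'
#' @param mirnaTargetLogFC Log2 fold change (miliary solid vs rest) applied
#'   to coding targets of the designated up-miRNAs; the up-miRNAs themselves
#'   receive the opposite shift \code{-mirnaTargetLogFC}, so a negative value
#'   plants "miRNAs up, targets down".
#' @param lncrnaMiliaryLogFC Global log2 shift of all lncRNA features in
#'   miliary solid (P/M) samples.
#' @param circIndexShift Shift of the back-splice rate in miliary solid
#'   samples, on the logit scale.
#' @param signatureLogFC Log2 shift (+ for miliary-up members, - for
#'   non-miliary-up members) of the planted 13-member spread signature in
#'   miliary samples.
#' @param coxCoefficients Named vector of log-hazard-ratio effects used to
#'   simulate survival (default \code{\link{trainingCoxCoefficients}}).
#'
#' @return A validated list of class \code{"PlantedEffects"}.
#' @export
#' @examples
#' plantedEffects()                      # study-condition defaults
#' nullEffects <- plantedEffects(0, 0, 0, 0, coxCoefficients = c(predictor = 0))
plantedEffects <- function(mirnaTargetLogFC = -1, lncrnaMiliaryLogFC = -1,
                           circIndexShift = -0.5, signatureLogFC = 2,
                           coxCoefficients = trainingCoxCoefficients()) {
  eff <- list(mirnaTargetLogFC = mirnaTargetLogFC,
              lncrnaMiliaryLogFC = lncrnaMiliaryLogFC,
              circIndexShift = circIndexShift,
              signatureLogFC = signatureLogFC,
              coxCoefficients = coxCoefficients)
  if (!all(vapply(eff[1:4], function(e) is.finite(e), logical(1))) ||
      any(!is.finite(coxCoefficients)))
    stop("all planted effect sizes must be finite")
  class(eff) <- "PlantedEffects"
  eff
}

## feature id / biotype layout for a config
.featureTable <- function(cfg) {
  data.frame(
    feature_id = c(sprintf("gene%05d", seq_len(cfg$nCoding)),
                   sprintf("lnc%04d", seq_len(cfg$nLncRNA)),
                   sprintf("miR-%04d", seq_len(cfg$nMiRNA)),
                   sprintf("piR-%04d", seq_len(cfg$nPiRNA)),
                   sprintf("snRNA-%03d", seq_len(cfg$nSnRNA)),
                   sprintf("snoRNA-%03d", seq_len(cfg$nSnoRNA))),
    biotype = rep(biotypeLevels(),
                  times = c(cfg$nCoding, cfg$nLncRNA, cfg$nMiRNA,
                            cfg$nPiRNA, cfg$nSnRNA, cfg$nSnoRNA)),
    stringsAsFactors = FALSE)
}

## relative library mass per biotype in a small-RNA + rRNA-depleted design
.biotypeMass <- c(coding = 0.35, lncRNA = 0.10, miRNA = 0.40,
                  piRNA = 0.10, snRNA = 0.02, snoRNA = 0.03)

#' Generate a synthetic spread-type cohort
#'
#' Draws a complete synthetic cohort: negative-binomial raw counts around
#' biotype-specific baseline abundances with per-patient biological random
#' effects shared across each patient's ascitic and solid samples; per-sample
#' back-splice / linear splice junction events; a miRNA-to-target interaction
#' table; a gene-set collection partly built around targets of the designated
#' up-miRNAs; per-patient survival records; and an echo of the planted truth
#' for recovery tests.
#'
#' Planted group structure (all governed by \code{effects}): lncRNA features
#' and the back-splice rate are shifted in miliary solid (P/M) samples;
#' coding targets of the up-miRNAs are shifted in miliary solid samples while
#' the up-miRNAs themselves move oppositely; the 13 planted signature
#' members (3 miliary-up, 10 non-miliary-up: 8 miRNAs + 2 piRNAs) are
#' shifted in all miliary samples; survival times are exponential with
#' log-hazard equal to the covariate effects, the spread type entering as the
#' \code{predictor} covariate.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param effects A \code{\link{plantedEffects}}.
#' @param seed Integer seed (defaults to \code{config$seed}).
#'
#' @return A list of class \code{"SyntheticCohort"} with elements
#'   \code{counts} (a raw-scale \code{\linkS4class{SpreadExperiment}} whose
#'   \code{colData} holds patient, tissue and spread), \code{junctions}
#'   (data frame sample / back_splice_events / linear_splice_events),
#'   \code{annotations}, \code{targets} (mirna / gene / evidence),
#'   \code{geneSets} (named list of gene-id vectors), \code{survival}
#'   (one record per patient), and \code{truth}.
#' @seealso \code{\link{generateSurvival}}, \code{\link{writeCohort}}
#' @export
#' @examples
#' ch <- generateCohort(cohortConfig(nPatients = 6, nCoding = 50,
#'                                   nLncRNA = 20, nMiRNA = 40, nPiRNA = 10,
#'                                   nSnRNA = 5, nSnoRNA = 5,
#'                                   libSizeMean = 1e5, nGeneSets = 10))
#' ch$counts
generateCohort <- function(config = cohortConfig(),
                           effects = plantedEffects(),
                           seed = config$seed) {
  stopifnot(inherits(config, "CohortConfig"),
            inherits(effects, "PlantedEffects"))
  set.seed(seed)
  cfg <- config

  ## samples: patients x tissue origins, spread type at patient level
  nMil <- round(cfg$nPatients * cfg$spreadFraction)
  patients <- sprintf("pt%02d", seq_len(cfg$nPatients))
  spreadByPatient <- setNames(
    rep(c("miliary", "non-miliary"), c(nMil, cfg$nPatients - nMil)), patients)
  ann <- expand.grid(patient = patients, tissue = cfg$tissueOrigins,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann <- ann[order(ann$patient, ann$tissue), , drop = FALSE]
  ann$sample <- paste(ann$patient, ann$tissue, sep = "_")
  ann$spread <- spreadByPatient[ann$patient]
  rownames(ann) <- ann$sample
  S <- nrow(ann)
  solid <- ann$tissue %in% c("P", "M")
  miliary <- ann$spread == "miliary"

  ## features and baseline relative abundances
  feat <- .featureTable(cfg)
  F <- nrow(feat)
  if (F == 0L) stop("configuration defines no features")
  mass <- .biotypeMass[unique(feat$biotype)]
  mass <- mass / sum(mass)
  w <- rlnorm(F, meanlog = 0, sdlog = 1.5)
  prop <- numeric(F)
  for (bt in names(mass)) {
    i <- feat$biotype == bt
    prop[i] <- mass[[bt]] * w[i] / sum(w[i])
  }

  ## miRNA -> coding target interactions
  mirIds <- feat$feature_id[feat$biotype == "miRNA"]
  codingIds <- feat$feature_id[feat$biotype == "coding"]
  targets <- NULL
  if (length(mirIds) && length(codingIds)) {
    nt <- pmin(pmax(rpois(length(mirIds), cfg$meanTargetsPerMiRNA), 1L),
               length(codingIds))
    targets <- data.frame(
      mirna = rep(mirIds, nt),
      gene = unlist(lapply(nt, function(k) sample(codingIds, k))),
      evidence = "verified", stringsAsFactors = FALSE)
    targets <- unique(targets)
  }
  upMirs <- head(mirIds, cfg$nUpMiRNAs)
  suppressed <- if (is.null(targets)) character() else
    unique(targets$gene[targets$mirna %in% upMirs])

  ## gene sets: planted sets drawn mostly from up-miR targets
  geneSets <- list()
  plantedSets <- character()
  if (cfg$nGeneSets > 0 && length(codingIds)) {
    nPlanted <- round(cfg$nGeneSets * cfg$plantedSetFraction)
    sizes <- sample(seq(cfg$setSizeRange[1], cfg$setSizeRange[2]),
                    cfg$nGeneSets, replace = TRUE)
    sizes <- pmin(sizes, length(codingIds))
    geneSets <- vector("list", cfg$nGeneSets)
    names(geneSets) <- sprintf("set%03d", seq_len(cfg$nGeneSets))
    for (i in seq_len(cfg$nGeneSets)) {
      if (i <= nPlanted && length(suppressed) >= 2) {
        nIn <- min(round(0.8 * sizes[i]), length(suppressed))
        geneSets[[i]] <- unique(c(sample(suppressed, nIn),
                                  sample(codingIds, sizes[i] - nIn)))
      } else {
        geneSets[[i]] <- sample(codingIds, sizes[i])
      }
    }
    plantedSets <- names(geneSets)[seq_len(nPlanted)]
  }

  ## planted signature members: 3 miliary-up miRNAs, 8 + 2 non-miliary-up
  sigUp <- sigDown <- character()
  piIds <- feat$feature_id[feat$biotype == "piRNA"]
  freeMirs <- setdiff(mirIds, upMirs)
  if (length(freeMirs) >= 11 && length(piIds) >= 2) {
    sigUp <- freeMirs[1:3]
    sigDown <- c(freeMirs[4:11], piIds[1:2])
  }

  ## log2 effect matrix
  E <- matrix(0, F, S, dimnames = list(feat$feature_id, ann$sample))
  milSolid <- miliary & solid
  if (any(milSolid)) {
    E[feat$biotype == "lncRNA", milSolid] <-
      E[feat$biotype == "lncRNA", milSolid] + effects$lncrnaMiliaryLogFC
    if (length(upMirs)) {
      E[upMirs, milSolid] <- E[upMirs, milSolid] - effects$mirnaTargetLogFC
      if (length(suppressed))
        E[suppressed, milSolid] <-
          E[suppressed, milSolid] + effects$mirnaTargetLogFC
    }
  }
  if (length(sigUp) && any(miliary)) {
    E[sigUp, miliary] <- E[sigUp, miliary] + effects$signatureLogFC
    E[sigDown, miliary] <- E[sigDown, miliary] - effects$signatureLogFC
  }

  ## patient-level biological random effects, shared across a patient's samples
  Z <- matrix(rnorm(F * cfg$nPatients, 0, cfg$patientSd), F, cfg$nPatients,
              dimnames = list(feat$feature_id, patients))

  libs <- cfg$libSizeMean * rlnorm(S, -cfg$libSizeSpread^2 / 2,
                                   cfg$libSizeSpread)
  mu <- (prop %o% libs) * 2^(E + Z[, ann$patient])
  counts <- matrix(
    if (cfg$nbDispersion > 0)
      rnbinom(F * S, mu = mu, size = 1 / cfg$nbDispersion)
    else rpois(F * S, lambda = mu),
    F, S, dimnames = list(feat$feature_id, ann$sample))

  se <- SpreadExperiment(counts, biotype = feat$biotype,
                         colData = ann[, c("patient", "tissue", "spread")])

  ## splice-junction events
  total <- rpois(S, cfg$junctionDepth)
  logitP <- stats::qlogis(cfg$backSpliceRate) + rnorm(S, 0, 0.15) +
    ifelse(milSolid, effects$circIndexShift, 0)
  back <- rbinom(S, total, stats::plogis(logitP))
  junctions <- data.frame(sample = ann$sample,
                          back_splice_events = back,
                          linear_splice_events = total - back,
                          stringsAsFactors = FALSE)

  ## survival, one record per patient, spread type as the predictor covariate
  covs <- .defaultCovariates(cfg$nPatients)
  covs$predictor <- as.integer(spreadByPatient == "miliary")
  surv <- .simulateSurvival(covs, effects$coxCoefficients,
                            censorRate = 87 / 165)
  surv <- cbind(patient_id = patients, surv)

  out <- list(
    counts = se, junctions = junctions,
    annotations = ann[, c("sample", "patient", "tissue", "spread")],
    targets = targets, geneSets = geneSets, survival = surv,
    truth = list(effects = effects, upMiRNAs = upMirs,
                 suppressedGenes = suppressed, plantedSets = plantedSets,
                 signature = if (length(sigUp))
                   SpreadSignature(sigUp, sigDown) else NULL,
                 spreadByPatient = spreadByPatient))
  class(out) <- "SyntheticCohort"
  out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d features x %d samples, %d patients\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$annotations$patient))))
  cat(sprintf("  spread: %s\n",
              paste(names(table(x$annotations$spread)),
                    table(x$annotations$spread) /
                      length(unique(x$annotations$tissue)),
                    collapse = " / ")))
  cat(sprintf("  %d gene sets (%d planted), %d target interactions\n",
              length(x$geneSets), length(x$truth$plantedSets),
              if (is.null(x$targets)) 0L else nrow(x$targets)))
  invisible(x)
}

## default clinicopathological covariate generators
.defaultCovariates <- function(n) {
  data.frame(
    age_decades = rnorm(n, 5.8, 1.2),
    figo = sample(0:2, n, replace = TRUE, prob = c(0.08, 0.72, 0.20)),
    residual = rbinom(n, 1, 0.45),
    grade = rbinom(n, 1, 0.75),
    predictor = rbinom(n, 1, 0.5))
}

## exponential event times with administrative uniform censoring tuned to
## the target censoring fraction (tau solved from the marginal censoring
## probability of the exponential model)
.simulateSurvival <- function(covariates, coefficients,
                              censorRate, baselineMedian = 45) {
  n <- nrow(covariates)
  X <- as.matrix(covariates[, names(coefficients), drop = FALSE])
  lp <- drop(X %*% coefficients)
  lambda <- log(2) / baselineMedian * exp(lp - mean(lp))
  tt <- rexp(n, rate = lambda)
  if (censorRate <= 0) {
    event <- rep(1L, n); time <- tt
  } else {
    pcens <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau))
    tau <- uniroot(function(x) pcens(x) - censorRate,
                   interval = c(1e-6, 1e8), tol = 1e-8)$root
    cens <- runif(n, 0, tau)
    event <- as.integer(tt <= cens)
    time <- pmin(tt, cens)
  }
  cbind(covariates,
        data.frame(time_months = time, event = event))
}

#' Simulate survival records under a proportional-hazards model
#'
#' Generates subjects with clinicopathological covariates (age in decades,
#' ordinal FIGO stage, residual tumor, grade, and a binary spread predictor),
#' exponential event times whose log-hazard is the linear predictor under
#' the supplied coefficients, and uniform administrative censoring tuned so
#' the expected censored fraction equals \code{censorRate}. The default
#' coefficients are the published training-cohort Cox effects and the
#' default censoring fraction matches a cohort of 165 patients with 78
#' events.
#'
#' @param n Number of subjects.
#' @param coefficients Named log-hazard-ratio effects; covariates without a
#'   generator in \code{covariateDistributions} or among the built-in
#'   defaults are drawn as balanced Bernoulli variables.
#' @param covariateDistributions Optional named list of functions
#'   \code{n -> values} overriding the covariate generators.
#' @param censorRate Target censored fraction in [0, 1).
#' @param baselineMedian Median survival (months) of an average-risk subject.
#' @param seed Optional integer seed.
#'
#' @return Data frame with the covariates plus \code{time_months} and
#'   \code{event}.
#' @seealso \code{\link{fitCoxModel}}
#' @export
#' @examples
#' surv <- generateSurvival(n = 165, seed = 3)
#' sum(surv$event)   # close to 78
generateSurvival <- function(n, coefficients = trainingCoxCoefficients(),
                             covariateDistributions = NULL,
                             censorRate = 87 / 165, baselineMedian = 45,
                             seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must be in [0, 1)")
  if (baselineMedian <= 0) stop("baselineMedian must be positive")
  if (!is.null(seed)) set.seed(seed)
  defaults <- .defaultCovariates(n)
  covs <- as.data.frame(lapply(setNames(nm = names(coefficients)),
    function(nm) {
      if (!is.null(covariateDistributions[[nm]]))
        covariateDistributions[[nm]](n)
      else if (nm %in% colnames(defaults)) defaults[[nm]]
      else rbinom(n, 1, 0.5)
    }))
  .simulateSurvival(covs, coefficients, censorRate, baselineMedian)
}
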