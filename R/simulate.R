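#' Configuration for the synthetic drug--ADR generator
#'
#' The generator plants a latent-mechanism structure: each of
#' \code{nLatent} mechanisms (think "a protein/pathway a drug acts on")
#' governs a random subset of ADRs and a random subset of feature columns;
#' each drug carries a random subset of mechanisms with heavy-tailed
#' (Zipf-like) mechanism popularity. A drug causes an ADR governed by one of
#' its mechanisms with probability \code{linkStrength}, and any other ADR
#' with probability \code{adrBaseRate}; its governed feature bits are set to
#' 1 and every feature bit is then flipped with probability
#' \code{featureNoise}. Drugs sharing mechanisms therefore share both ADRs
#' and features, which is the dependency structure the drug-to-drug network
#' analysis exploits.
#'
#' The defaults are a one-tenth-scale analogue of an 832-drug, 1385-ADR
#' pharmacological dataset with six one-hot feature categories, with
#' \code{featureNoise = 0.5} (feature bits pure noise) so that any
#' predictive signal reaching the classifiers must travel through the
#' network features.
#'
#' @param nDrugs,nAdrs number of drugs and ADRs.
#' @param blockWidths six positive integers: widths of the chemical, enzyme,
#'   indication, pathway, target and transporter one-hot blocks.
#' @param nLatent number of latent mechanisms (must not exceed \code{nAdrs}).
#' @param adrBaseRate probability a drug shows an ADR none of its
#'   mechanisms governs.
#' @param linkStrength probability a mechanism carried by a drug activates
#'   each ADR it governs.
#' @param featureNoise per-bit flip probability applied to the feature
#'   blocks (0.5 = features carry no information).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @param zipfExponent exponent of the Zipf-like mechanism popularity decay.
#' @param governProb probability a mechanism governs any given ADR or
#'   feature column.
#' @param meanMechanisms target mean number of mechanisms per drug (scales
#'   the popularity curve).
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nDrugs = 200L, nAdrs = 150L,
                             blockWidths = c(chemical = 88L, enzyme = 11L,
                                             indication = 87L, pathway = 17L,
                                             target = 79L, transporter = 7L),
                             nLatent = 25L, adrBaseRate = 0.02,
                             linkStrength = 0.8, featureNoise = 0.5,
                             seed = 1L, zipfExponent = 1.5,
                             governProb = 0.1, meanMechanisms = 2) {
    cfg <- list(nDrugs = as.integer(nDrugs), nAdrs = as.integer(nAdrs),
                blockWidths = blockWidths, nLatent = as.integer(nLatent),
                adrBaseRate = adrBaseRate, linkStrength = linkStrength,
                featureNoise = featureNoise, seed = as.integer(seed),
                zipfExponent = zipfExponent, governProb = governProb,
                meanMechanisms = meanMechanisms)
    probs <- c(adrBaseRate = adrBaseRate, linkStrength = linkStrength,
               featureNoise = featureNoise, governProb = governProb)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]: ",
             paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
    counts <- c(nDrugs = cfg$nDrugs, nAdrs = cfg$nAdrs, nLatent = cfg$nLatent)
    if (any(counts < 1L)) stop("counts must be >= 1")
    if (length(blockWidths) != 6L || any(blockWidths < 1))
        stop("blockWidths must be exactly six positive integers")
    if (is.null(names(cfg$blockWidths)))
        names(cfg$blockWidths) <- c("chemical", "enzyme", "indication",
                                    "pathway", "target", "transporter")
    if (cfg$nLatent > cfg$nAdrs)
        stop("degenerate design: nLatent (", cfg$nLatent,
             ") exceeds nAdrs (", cfg$nAdrs, ")")
    structure(cfg, class = "SimulationConfig")
}

#' Simulate a drug--ADR dataset with planted latent mechanisms
#'
#' See \code{\link{simulationConfig}} for the generative model. Mechanism
#' popularity follows a Zipf-like curve, so a few mechanisms are carried by
#' many drugs and most by a handful — reproducing the right-skewed ADR
#' frequency distribution (many ADRs caused by very few drugs) that
#' motivates the minimum-frequency filter and SMOTE rebalancing downstream.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list of class \code{"SyntheticAdrData"} with elements
#'   \code{incidence} (an \linkS4class{AdrIncidence}), \code{features}
#'   (a \linkS4class{DrugFeatureSet}) and \code{latentAssignment} (named
#'   list, drug -> integer vector of carried mechanisms; diagnostic ground
#'   truth, never consumed by pipeline stages).
#' @examples
#' sim <- simulateAdrData(simulationConfig(nDrugs = 30, nAdrs = 20,
#'     blockWidths = rep(4, 6), nLatent = 5, seed = 7))
#' dim(incidenceMatrix(sim$incidence))
#' @export
simulateAdrData <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
    nD <- cfg$nDrugs; nA <- cfg$nAdrs; nM <- cfg$nLatent
    drugs <- sprintf("d%03d", seq_len(nD))
    adrs <- sprintf("a%03d", seq_len(nA))

    # Zipf-like carry probability per mechanism, scaled to the target mean
    pop <- seq_len(nM)^(-cfg$zipfExponent)
    pop <- pmin(1, cfg$meanMechanisms * pop / sum(pop))

    carrier <- matrix(stats::runif(nD * nM) < rep(pop, each = nD), nD, nM)
    none <- which(rowSums(carrier) == 0L)
    for (d in none)  # every drug carries at least one mechanism
        carrier[d, sample.int(nM, 1L, prob = pop)] <- TRUE

    governAdr <- matrix(stats::runif(nM * nA) < cfg$governProb, nM, nA)
    totalW <- sum(cfg$blockWidths)
    governFeat <- matrix(stats::runif(nM * totalW) < cfg$governProb, nM, totalW)

    governed <- (carrier %*% governAdr) > 0            # drug x ADR
    pLink <- ifelse(governed, cfg$linkStrength, cfg$adrBaseRate)
    incidence <- matrix(as.numeric(stats::runif(nD * nA) < pLink), nD, nA,
                        dimnames = list(drugs, adrs))

    base <- (carrier %*% governFeat) > 0               # drug x feature
    flip <- matrix(stats::runif(nD * totalW) < cfg$featureNoise, nD, totalW)
    feat <- matrix(as.numeric(xor(base, flip)), nD, totalW)
    rownames(feat) <- drugs

    splits <- rep(names(cfg$blockWidths), cfg$blockWidths)
    blocks <- lapply(names(cfg$blockWidths), function(nm) {
        b <- feat[, splits == nm, drop = FALSE]
        colnames(b) <- sprintf("%s_%03d", nm, seq_len(ncol(b)))
        b
    })
    names(blocks) <- names(cfg$blockWidths)

    latent <- apply(carrier, 1L, which, simplify = FALSE)
    names(latent) <- drugs

    structure(list(incidence = AdrIncidence(incidence),
                   features = DrugFeatureSet(blocks),
                   latentAssignment = latent,
                   config = cfg),
              class = "SyntheticAdrData")
}

#' Per-ADR drug-count frequency profile
#'
#' Counts, for each ADR, how many drugs are associated with it. The sum over
#' ADRs equals the total number of 1-entries in the incidence matrix. This
#' is the quantity the minimum-frequency eligibility filter
#' (\code{\link{filterAdrs}}) thresholds.
#'
#' @param incidence an \linkS4class{AdrIncidence}.
#' @return named integer vector, one count per ADR in original order.
#' @export
adrFrequency <- function(incidence) {
    stopifnot(is(incidence, "AdrIncidence"))
    counts <- colSums(incidenceMatrix(incidence))
    storage.mode(counts) <- "integer"
    counts
}
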