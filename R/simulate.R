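#' Simulation configuration for synthetic simplex-family cohorts
#'
#' Bundles and validates the parameters of the cohort generator. The
#' defaults describe the study conditions the package is designed around:
#' quad families (two parents, an affected proband, an unaffected sibling),
#' background variants at moderate minor-allele frequencies, a planted set
#' of pairwise-interacting risk variants whose joint carriers have elevated
#' case liability, rare de novo events, strongly male-biased case
#' ascertainment (86.8% male probands vs 47.4% male controls), and a small
#' rate of low-allele-depth somatic-like artifact genotypes.
#'
#' @param nFamilies number of quad families.
#' @param nVariants number of variants in the panel.
#' @param nPlantedPairs number of planted interacting variant pairs.
#' @param pairRelativeRisk joint-carrier odds multiplier per planted pair
#'   (applied on the logit scale as `log(pairRelativeRisk)`).
#' @param baselineLiability baseline probability of case liability for a
#'   child carrying no planted pair. The default `NULL` auto-calibrates
#'   it so that the effective affection threshold (the pair count at
#'   which `P(affected)` crosses 1/2) sits about three standard deviations
#'   above the expected planted-pair load: affection then requires an
#'   unusually high polygenic burden, the proband is a genuine upper
#'   tail while parents and the sibling remain near the population mean,
#'   and the architecture is recoverable at cohort scale.
#' @param mafRange length-2 numeric range of background alternate-allele
#'   frequencies.
#' @param plantedInformativeFraction fraction of families in which a
#'   planted pair segregates: one randomly chosen parent is heterozygous
#'   at both loci of the pair (a risk haplotype in cis), the other
#'   parent homozygous reference. Every such family is
#'   transmission-informative in the TDT sense — each child's carrier
#'   status is an independent transmission coin — which removes
#'   between-family allele-frequency variance at the risk loci and makes
#'   the planted architecture identifiable at desk scale. In the
#'   remaining families both parents lack the alleles, leaving room for
#'   de novo events.
#' @param plantedPairLinkage probability that the two members of a
#'   planted pair co-transmit within a family (the pairs are placed at
#'   adjacent loci on the same chromosome, so co-transmission is
#'   ordinary linkage). Partial linkage keeps each variant's marginal
#'   association weaker than the pair's joint association while making
#'   both detectable.
#' @param deNovoRate per-child, per-planted-risk-variant probability of a
#'   de novo event (only where both parents lack the allele).
#' @param backgroundDeNovoRate per-child, per-variant background de novo
#'   rate on non-planted variants.
#' @param maleCaseFraction target proband male fraction (default 0.868).
#' @param controlMaleFraction sibling male fraction (default 0.474).
#' @param somaticNoiseRate probability that a homozygous-reference genotype
#'   is written as a low-allele-depth artifact heterozygote (alt fraction
#'   strictly below 0.25).
#' @param meanDepth mean sequencing depth for allele-depth emission.
#' @param xFraction fraction of panel variants placed on chromosome X.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @return a validated `SimulationConfig` (a classed list).
#' @export
simulationConfig <- function(nFamilies = 300L, nVariants = 2000L,
                             nPlantedPairs = 20L, pairRelativeRisk = 150,
                             baselineLiability = NULL,
                             mafRange = c(0.05, 0.4),
                             plantedInformativeFraction = 0.95,
                             plantedPairLinkage = 0.2,
                             deNovoRate = 0.01,
                             backgroundDeNovoRate = 1e-4,
                             maleCaseFraction = 0.868,
                             controlMaleFraction = 0.474,
                             somaticNoiseRate = 0.002,
                             meanDepth = 40L, xFraction = 0.05,
                             seed = 1L) {
  if (is.null(baselineLiability)) {
    # place the affection threshold 3 sd ABOVE the expected planted
    # pair load: affection requires an unusually high polygenic burden,
    # so the proband is the upper tail while parents and sibling sit at
    # the population mean
    q <- plantedInformativeFraction * 0.5 *
      (plantedPairLinkage + (1 - plantedPairLinkage) * 0.5)
    n <- as.integer(nPlantedPairs)
    tstar <- if (n > 0L)
      min(n - 0.5, n * q + 3 * sqrt(n * q * (1 - q))) else 0
    baselineLiability <- stats::plogis(
      -(tstar + 0.5) * log(pairRelativeRisk))
  }
  cfg <- list(nFamilies = as.integer(nFamilies),
              nVariants = as.integer(nVariants),
              nPlantedPairs = as.integer(nPlantedPairs),
              pairRelativeRisk = pairRelativeRisk,
              baselineLiability = baselineLiability,
              mafRange = as.numeric(mafRange),
              plantedInformativeFraction = plantedInformativeFraction,
              plantedPairLinkage = plantedPairLinkage,
              deNovoRate = deNovoRate,
              backgroundDeNovoRate = backgroundDeNovoRate,
              maleCaseFraction = maleCaseFraction,
              controlMaleFraction = controlMaleFraction,
              somaticNoiseRate = somaticNoiseRate,
              meanDepth = as.integer(meanDepth),
              xFraction = xFraction,
              seed = as.integer(seed))
  probs <- c(cfg$baselineLiability, cfg$mafRange,
             cfg$plantedInformativeFraction, cfg$plantedPairLinkage,
             cfg$deNovoRate,
             cfg$backgroundDeNovoRate, cfg$maleCaseFraction,
             cfg$controlMaleFraction, cfg$somaticNoiseRate, cfg$xFraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$nFamilies >= 1L, cfg$nVariants >= 1L,
            cfg$nPlantedPairs * 2L <= cfg$nVariants,
            cfg$pairRelativeRisk > 0, cfg$meanDepth >= 1L,
            cfg$mafRange[1] <= cfg$mafRange[2])
  if (cfg$baselineLiability == 0 && cfg$nPlantedPairs == 0L)
    stop("no achievable case per family: baseline liability 0 and no planted pairs")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Build the variant panel: chromosomes, spaced positions, ref/alt, MAF.
makePanel <- function(cfg) {
  nV <- cfg$nVariants
  nX <- round(cfg$xFraction * nV)
  chrom <- c(paste0("chr", sort(rep_len(1:22, nV - nX))),
             rep("chrX", nX))
  pos <- integer(nV)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    # spacing >= 2000 keeps synthetic gene intervals non-overlapping
    pos[idx] <- cumsum(sample(2000:9999, length(idx), replace = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nV, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(id = variantId(chrom, pos, ref, alt),
             chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             maf = runif(nV, cfg$mafRange[1], cfg$mafRange[2]),
             chrom_class = chromClass(chrom),
             stringsAsFactors = FALSE)
}

#' Simulate a simplex-family cohort with planted pairwise interactions
#'
#' Generates parental genotypes per variant from the panel allele
#' frequencies, transmits alleles to two children by Mendelian inheritance,
#' and injects de novo events where both parents lack the allele. Each
#' child's affection status is Bernoulli in its logistic liability:
#' `logit P(affected) = qlogis(baselineLiability) +
#' log(pairRelativeRisk) * (number of planted pairs with both variants
#' carried)`. Families are then ascertained as simplex — exactly one
#' affected child, who becomes the proband — by rejection sampling, which
#' is what enriches joint carriers among probands and depletes them among
#' the unaffected siblings, as in real simplex collections. Because
#' affection depends only on the planted variants, ascertainment is run on
#' those columns alone and the rest of the genome is drawn afterwards for
#' the accepted families (statistically exact and fast); with no planted
#' pairs, affection is independent of genotype and the proband is a
#' fair-coin child. The proband's sex is drawn from `maleCaseFraction` and
#' the sibling's from `controlMaleFraction`, emulating male-biased case
#' ascertainment. Somatic-like artifact genotypes (low alternate-depth
#' heterozygotes) are planted at `somaticNoiseRate` among
#' homozygous-reference genotypes; they count as present at allele-depth
#' threshold 0 and are removed deterministically at the 0.25 threshold.
#'
#' @param config a [simulationConfig()].
#' @return a `SimulatedCohort` list with elements `cohort`
#'   ([FamilyCohort-class]), `panel` (variant table), `genotypes`
#'   (integer 0/1/2 matrix, samples x variants), `presence`
#'   ([PresenceMatrix-class] at threshold 0, the ground truth for
#'   round-trip checks), `truth` (planted pairs, de novo events, artifact
#'   genotype index) and `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    nF <- cfg$nFamilies; nV <- cfg$nVariants
    panel <- makePanel(cfg)
    maf <- panel$maf

    # planted pairs are adjacent same-chromosome loci, so within-family
    # co-transmission (plantedPairLinkage) is ordinary linkage
    pairIdx <- if (cfg$nPlantedPairs > 0L) {
      sameChrom <- which(panel$chrom[-nV] == panel$chrom[-1L])
      starts <- sameChrom[seq(1L, length(sameChrom),
                              length.out = cfg$nPlantedPairs * 2L)]
      starts <- unique(starts[!(starts + 1L) %in% starts])
      starts <- starts[seq(1L, length(starts),
                           length.out = cfg$nPlantedPairs)]
      if (length(unique(starts)) < cfg$nPlantedPairs)
        stop("panel too small to place disjoint planted pairs")
      cbind(starts, starts + 1L)
    } else matrix(integer(0), ncol = 2L)

    # --- ascertainment phase: planted columns only ---
    plantedCols <- sort(unique(as.vector(pairIdx)))
    m <- length(plantedCols)
    baseLogit <- stats::qlogis(max(cfg$baselineLiability,
                                   1e-300))
    if (m > 0L) {
      localPair <- matrix(match(pairIdx, plantedCols), ncol = 2L)
      drawBatch <- function(B) {
        # carrier-parent design: in an informative family-pair, one
        # randomly chosen parent is heterozygous at BOTH loci of the
        # pair (a risk haplotype in cis); the other parent is hom-ref.
        # Children inherit the first member as a fair coin and the
        # second co-transmits with probability plantedPairLinkage
        # (ordinary linkage on the carrier haplotype). In the remaining
        # families both parents lack the alleles (de novo eligible).
        nP <- nrow(localPair)
        infPair <- matrix(runif(B * nP) < cfg$plantedInformativeFraction,
                          B, nP)
        carrierFather <- matrix(runif(B * nP) < 0.5, B, nP)
        FGp <- matrix(0L, B, m); MGp <- matrix(0L, B, m)
        for (p in seq_len(nP)) {
          i1 <- localPair[p, 1L]; i2 <- localPair[p, 2L]
          fa <- infPair[, p] & carrierFather[, p]
          mo <- infPair[, p] & !carrierFather[, p]
          FGp[fa, c(i1, i2)] <- 1L
          MGp[mo, c(i1, i2)] <- 1L
        }
        child <- function() {
          g <- matrix(0L, B, m)
          for (p in seq_len(nP)) {
            i1 <- localPair[p, 1L]; i2 <- localPair[p, 2L]
            t1 <- infPair[, p] & (runif(B) < 0.5)
            co <- runif(B) < cfg$plantedPairLinkage
            t2 <- infPair[, p] &
              ifelse(co, t1, runif(B) < 0.5)
            g[t1, i1] <- 1L
            g[t2, i2] <- 1L
          }
          g
        }
        C1p <- child(); C2p <- child()
        elig <- FGp == 0L & MGp == 0L
        dn <- function(ch) {
          hit <- elig & matrix(runif(B * m) < cfg$deNovoRate, B, m)
          ch[hit] <- 1L
          list(ch = ch, hit = hit)
        }
        d1 <- dn(C1p); d2 <- dn(C2p)
        liab <- function(ch) {
          L <- rep(baseLogit, B)
          carrier <- ch > 0L
          for (r in seq_len(nrow(localPair)))
            L <- L + log(cfg$pairRelativeRisk) *
              (carrier[, localPair[r, 1L]] & carrier[, localPair[r, 2L]])
          L
        }
        A1 <- runif(B) < stats::plogis(liab(d1$ch))
        A2 <- runif(B) < stats::plogis(liab(d2$ch))
        list(FGp = FGp, MGp = MGp, C1p = d1$ch, C2p = d2$ch,
             dn1 = d1$hit, dn2 = d2$hit, accept = xor(A1, A2),
             probandIsC1 = A1)
      }
      got <- list(); nAcc <- 0L; tries <- 0L; nTried <- 0
      while (nAcc < nF) {
        tries <- tries + 1L
        if (tries > 60L)
          stop("simplex ascertainment failed: no family with exactly one ",
               "affected child; liability configuration is degenerate")
        accRate <- if (tries > 1L) max(nAcc / nTried, 1e-4) else 0.03
        B <- min(max(4000L, ceiling(1.5 * (nF - nAcc) / accRate)),
                 500000L)
        nTried <- nTried + B
        b <- drawBatch(B)
        keep <- which(b$accept)
        if (length(keep)) {
          got[[length(got) + 1L]] <- lapply(
            b[c("FGp", "MGp", "C1p", "C2p", "dn1", "dn2")],
            function(x) x[keep, , drop = FALSE])
          got[[length(got)]]$probandIsC1 <- b$probandIsC1[keep]
          nAcc <- nAcc + length(keep)
        }
      }
      take <- function(el) {
        x <- do.call(rbind, lapply(got, `[[`, el))
        x[seq_len(nF), , drop = FALSE]
      }
      FGp <- take("FGp"); MGp <- take("MGp")
      C1p <- take("C1p"); C2p <- take("C2p")
      dn1p <- take("dn1"); dn2p <- take("dn2")
      probandIsC1 <- do.call(c, lapply(got, `[[`, "probandIsC1"))[
        seq_len(nF)]
    } else {
      probandIsC1 <- runif(nF) < 0.5
    }

    # --- rest of the genome for the accepted families ---
    drawParents <- function() {
      matrix(rbinom(nF * nV, 2L, rep(maf, each = nF)), nF, nV)
    }
    FG <- drawParents(); MG <- drawParents()
    transmit <- function() {
      matrix(rbinom(nF * nV, 1L, as.vector(FG) / 2), nF, nV) +
        matrix(rbinom(nF * nV, 1L, as.vector(MG) / 2), nF, nV)
    }
    C1 <- transmit(); C2 <- transmit()

    # background de novo events where both parents are hom-ref
    eligible <- FG == 0L & MG == 0L
    dnDraw <- function(child) {
      hit <- eligible &
        matrix(runif(nF * nV) < cfg$backgroundDeNovoRate, nF, nV)
      child[hit] <- 1L
      list(child = child, hit = hit)
    }
    d1 <- dnDraw(C1); C1 <- d1$child
    d2 <- dnDraw(C2); C2 <- d2$child
    hit1 <- d1$hit; hit2 <- d2$hit

    # overwrite planted columns with the ascertainment draws
    if (m > 0L) {
      FG[, plantedCols] <- FGp; MG[, plantedCols] <- MGp
      C1[, plantedCols] <- C1p; C2[, plantedCols] <- C2p
      hit1[, plantedCols] <- dn1p; hit2[, plantedCols] <- dn2p
    }
    d1 <- list(events = which(hit1, arr.ind = TRUE))
    d2 <- list(events = which(hit2, arr.ind = TRUE))

    probandSex <- ifelse(runif(nF) < cfg$maleCaseFraction, "M", "F")
    siblingSex <- ifelse(runif(nF) < cfg$controlMaleFraction, "M", "F")

    famId <- sprintf("FAM%05d", seq_len(nF))
    ids <- list(fa = paste0(famId, "_fa"), mo = paste0(famId, "_mo"),
                c1 = paste0(famId, "_c1"), c2 = paste0(famId, "_c2"))
    probandId <- ifelse(probandIsC1, ids$c1, ids$c2)
    siblingId <- ifelse(probandIsC1, ids$c2, ids$c1)
    c1Sex <- ifelse(probandIsC1, probandSex, siblingSex)
    c2Sex <- ifelse(probandIsC1, siblingSex, probandSex)

    sampleOrder <- as.vector(rbind(ids$fa, ids$mo, ids$c1, ids$c2))
    G <- matrix(0L, 4L * nF, nV,
                dimnames = list(sampleOrder, panel$id))
    G[ids$fa, ] <- FG; G[ids$mo, ] <- MG
    G[ids$c1, ] <- C1; G[ids$c2, ] <- C2
    rm(FG, MG, eligible)

    # somatic-like artifacts among hom-ref genotypes
    noiseIdx <- integer(0)
    if (cfg$somaticNoiseRate > 0) {
      homRef <- which(G == 0L)
      nNoise <- rbinom(1L, length(homRef), cfg$somaticNoiseRate)
      if (nNoise > 0L)
        noiseIdx <- sort(homRef[sample.int(length(homRef), nNoise)])
      rm(homRef)
    }

    P <- G > 0L
    P[noiseIdx] <- TRUE

    samples <- data.frame(
      sample_id = sampleOrder,
      family_id = rep(famId, each = 4L),
      role = "other", sex = "F", affected = FALSE,
      stringsAsFactors = FALSE)
    rownames(samples) <- samples$sample_id
    samples[ids$fa, c("role", "sex")] <- list("father", "M")
    samples[ids$mo, c("role", "sex")] <- list("mother", "F")
    samples[ids$c1, "role"] <- ifelse(probandIsC1, "proband", "sibling")
    samples[ids$c2, "role"] <- ifelse(probandIsC1, "sibling", "proband")
    samples[ids$c1, "sex"] <- c1Sex
    samples[ids$c2, "sex"] <- c2Sex
    samples[probandId, "affected"] <- TRUE
    rownames(samples) <- NULL

    famTab <- data.frame(
      family_id = famId, father_id = ids$fa, mother_id = ids$mo,
      proband_id = probandId, sibling_id = siblingId,
      proband_sex = probandSex, sibling_sex = siblingSex,
      control_designate_id = siblingId,
      stringsAsFactors = FALSE)
    cohort <- new("FamilyCohort", families = famTab, samples = samples)

    deNovo <- rbind(
      if (nrow(d1$events))
        data.frame(sample_id = ids$c1[d1$events[, "row"]],
                   variant = panel$id[d1$events[, "col"]]),
      if (nrow(d2$events))
        data.frame(sample_id = ids$c2[d2$events[, "row"]],
                   variant = panel$id[d2$events[, "col"]]))
    if (is.null(deNovo))
      deNovo <- data.frame(sample_id = character(0), variant = character(0))

    pm <- new("PresenceMatrix", presence = P,
              missing = matrix(FALSE, nrow(P), ncol(P),
                               dimnames = dimnames(P)),
              variants = panel[, c("id", "chrom", "pos", "ref", "alt",
                                   "chrom_class")],
              adThreshold = 0)

    truth <- list(
      plantedPairs = data.frame(
        idx1 = pairIdx[, 1L], idx2 = pairIdx[, 2L],
        id1 = panel$id[pairIdx[, 1L]], id2 = panel$id[pairIdx[, 2L]],
        logOddsPerPair = rep(log(cfg$pairRelativeRisk), nrow(pairIdx))),
      deNovo = deNovo, noiseIdx = noiseIdx)

    structure(list(cohort = cohort, panel = panel, genotypes = G,
                   presence = pm, truth = truth, config = cfg),
              class = "SimulatedCohort")
  })
}

#' Write a simulated cohort as VCF + PED (+ truth tables)
#'
#' Emits one multi-sample VCFv4.2 file with `GT:AD` genotypes, a 6-column
#' PED file, and two plain-text truth tables (`planted_pairs.tsv`,
#' `de_novo.tsv`). Allele depths are drawn binomially around the expected
#' alternate fraction (0.5 het, 1 hom-alt) at Poisson depth around
#' `meanDepth`; artifact genotypes are written as heterozygotes whose
#' alternate-depth fraction is strictly below 0.25, so the 25% filter
#' removes them deterministically. The header carries no timestamp, so
#' identical seed and configuration give byte-identical files. Re-ingesting
#' with [ingestCohort()] at threshold 0 reproduces the simulator's presence
#' matrix exactly (over sites with at least one carrier).
#'
#' @param sim a `SimulatedCohort` from [simulateCohort()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
emitVcfPed <- function(sim, outdir) {
  stopifnot(inherits(sim, "SimulatedCohort"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  cfg <- sim$config
  G <- sim$genotypes
  panel <- sim$panel
  nS <- nrow(G); nV <- ncol(G)

  withSeed(deriveSeed(cfg$seed, 7777L), {
    depth <- pmax(matrix(rpois(nS * nV, cfg$meanDepth), nS, nV), 1L)
    altReads <- matrix(0L, nS, nV)
    het <- G == 1L
    altReads[het] <- rbinom(sum(het), depth[het], 0.5)
    hom <- G == 2L
    altReads[hom] <- depth[hom]
    gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nS, nV)
    ni <- sim$truth$noiseIdx
    if (length(ni)) {
      d <- pmax(depth[ni], 8L)
      a <- pmax(1L, floor(runif(length(ni), 0.05, 0.245) * d))
      a <- pmin(a, ceiling(d / 4) - 1L)  # fraction strictly < 0.25
      depth[ni] <- d
      altReads[ni] <- a
      gt[ni] <- "0/1"
    }
    cells <- matrix(paste0(gt, ":", depth - altReads, ",", altReads),
                    nS, nV)

    header <- c("##fileformat=VCFv4.2",
                "##source=episcreen-simulator",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", rownames(G)),
                      collapse = "\t"))
    fixed <- paste(panel$chrom, panel$pos, ".", panel$ref, panel$alt,
                   ".", "PASS", ".", "GT:AD", sep = "\t")
    body <- do.call(paste,
                    c(list(fixed), as.data.frame(t(cells)), sep = "\t"))
    vcfPath <- file.path(outdir, "cohort.vcf")
    writeLines(c(header, body), vcfPath)
  })

  smp <- sampleInfo(sim$cohort)
  fam <- families(sim$cohort)
  isChild <- smp$role %in% c("proband", "sibling")
  fa <- fam$father_id[match(smp$family_id, fam$family_id)]
  mo <- fam$mother_id[match(smp$family_id, fam$family_id)]
  ped <- data.frame(
    family = smp$family_id, individual = smp$sample_id,
    father = ifelse(isChild, fa, "0"),
    mother = ifelse(isChild, mo, "0"),
    sex = ifelse(smp$sex == "M", 1L, 2L),
    phenotype = ifelse(smp$affected, 2L, 1L))
  pedPath <- file.path(outdir, "cohort.ped")
  write.table(ped, pedPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  ppPath <- file.path(outdir, "planted_pairs.tsv")
  write.table(sim$truth$plantedPairs, ppPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dnPath <- file.path(outdir, "de_novo.tsv")
  write.table(sim$truth$deNovo, dnPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(vcf = file.path(outdir, "cohort.vcf"), ped = pedPath,
                 planted_pairs = ppPath, de_novo = dnPath))
}
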