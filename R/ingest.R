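# cohort_io: VCF + PED ingestion, presence rules, gender policy, labels.

readPed <- function(pedPath) {
  ped <- read.table(pedPath, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("family", "individual", "father",
                                  "mother", "sex", "phenotype"))
  if (!nrow(ped)) stop("empty PED file: ", pedPath)
  ped
}

# Build a FamilyCohort from a 6-column PED table (quad families).
cohortFromPed <- function(ped) {
  fams <- split(ped, ped$family)
  rows <- lapply(fams, function(f) {
    if (nrow(f) != 4L)
      stop("family ", f$family[1], " is not a quad (has ",
           nrow(f), " members)")
    isChild <- f$father != "0" | f$mother != "0"
    children <- f[isChild, , drop = FALSE]
    parents <- f[!isChild, , drop = FALSE]
    if (nrow(children) != 2L)
      stop("family ", f$family[1], " must have exactly two children")
    fatherId <- unique(children$father)
    motherId <- unique(children$mother)
    if (length(fatherId) != 1L || length(motherId) != 1L ||
        !all(c(fatherId, motherId) %in% parents$individual))
      stop("family ", f$family[1], ": children do not share both parents")
    aff <- children$phenotype == 2L
    if (sum(aff) != 1L)
      stop("family ", f$family[1], " must have exactly one affected child")
    proband <- children[aff, ]
    sibling <- children[!aff, ]
    data.frame(family_id = f$family[1], father_id = fatherId,
               mother_id = motherId, proband_id = proband$individual,
               sibling_id = sibling$individual,
               proband_sex = ifelse(proband$sex == 1L, "M", "F"),
               sibling_sex = ifelse(sibling$sex == 1L, "M", "F"),
               control_designate_id = sibling$individual,
               stringsAsFactors = FALSE)
  })
  famTab <- do.call(rbind, rows)
  rownames(famTab) <- NULL
  role <- rep("other", nrow(ped))
  role[ped$individual %in% famTab$father_id] <- "father"
  role[ped$individual %in% famTab$mother_id] <- "mother"
  role[ped$individual %in% famTab$proband_id] <- "proband"
  role[ped$individual %in% famTab$sibling_id] <- "sibling"
  samples <- data.frame(sample_id = ped$individual,
                        family_id = ped$family, role = role,
                        sex = ifelse(ped$sex == 1L, "M", "F"),
                        affected = ped$phenotype == 2L,
                        stringsAsFactors = FALSE)
  new("FamilyCohort", families = famTab, samples = samples)
}

# Parse one VCF into per-sample presence/missing over split alt alleles.
parseVcfPresence <- function(vcfPath, minAdFraction) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))          # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  asMat <- function(x) {
    if (is.null(dim(x)))
      matrix(x, nrow = nrow(fix),
             dimnames = list(NULL, names(x)))
    else x
  }
  gtMat <- asMat(vcfR::extract.gt(vcf, element = "GT"))
  adMat <- if ("AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID)
    asMat(vcfR::extract.gt(vcf, element = "AD")) else NULL
  if (is.null(adMat) && minAdFraction > 0)
    stop("AD FORMAT field absent but min_ad_fraction > 0 in ", vcfPath)

  samples <- colnames(gtMat)
  altList <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  nAlt <- lengths(altList)
  recIdx <- rep(seq_len(nrow(fix)), nAlt)     # split multi-allelic records
  altIdx <- sequence(nAlt)
  vk <- data.frame(chrom = fix[recIdx, "CHROM"],
                   pos = as.integer(fix[recIdx, "POS"]),
                   ref = fix[recIdx, "REF"],
                   alt = unlist(altList),
                   stringsAsFactors = FALSE)
  vk$id <- variantId(vk$chrom, vk$pos, vk$ref, vk$alt)
  if (anyDuplicated(vk$id))
    stop("duplicate variant keys after multi-allelic split in ", vcfPath)

  gtExp <- gtMat[recIdx, , drop = FALSE]
  missing <- is.na(gtExp) | gtExp == "." | gtExp == "./." | gtExp == ".|."
  # presence of alt allele k: genotype string contains allele index k
  alleles <- gsub("|", "/", gtExp, fixed = TRUE)
  hasAlt <- matrix(FALSE, nrow(gtExp), ncol(gtExp))
  for (k in sort(unique(altIdx))) {
    rowsK <- altIdx == k
    pat <- paste0("(^|/)", k, "(/|$)")
    hasAlt[rowsK, ] <- grepl(pat, alleles[rowsK, , drop = FALSE]) &
      !missing[rowsK, , drop = FALSE]
  }

  if (minAdFraction > 0) {
    adExp <- adMat[recIdx, , drop = FALSE]
    need <- which(hasAlt)
    if (length(need)) {
      parts <- strsplit(adExp[need], ",", fixed = TRUE)
      kk <- altIdx[(need - 1L) %% nrow(adExp) + 1L]
      frac <- vapply(seq_along(need), function(i) {
        p <- suppressWarnings(as.numeric(parts[[i]]))
        if (length(p) <= kk[i] || anyNA(p[c(1L, kk[i] + 1L)])) return(NA_real_)
        a <- p[kk[i] + 1L]
        tot <- p[1L] + a       # alt depth / (ref depth + alt depth)
        if (tot <= 0) 0 else a / tot
      }, numeric(1))
      fail <- !is.na(frac) & frac < minAdFraction
      hasAlt[need[fail]] <- FALSE
      if (anyNA(frac))
        stop("malformed or absent AD at ", sum(is.na(frac)),
             " carrier genotypes while min_ad_fraction > 0 in ", vcfPath)
    }
  }
  dimnames(hasAlt) <- list(vk$id, samples)
  dimnames(missing) <- list(vk$id, samples)
  list(variants = vk, presence = t(hasAlt), missing = t(missing))
}

#' Ingest VCF + PED into a cohort and presence matrix
#'
#' Reads one or more multi-sample VCF files and a PED pedigree, splits
#' multi-allelic records, applies reference-variant removal (a
#' homozygous-reference genotype contributes absence) and the
#' allele-depth fraction filter (a carrier genotype passes iff
#' `alt_depth / (ref_depth + alt_depth) >= minAdFraction`; the boundary is
#' inclusive), applies the gender-mismatch policy, and returns the cohort
#' plus the bit-testable presence matrix. Sites left with zero carriers are
#' dropped unless `dropEmpty = FALSE`. With several VCFs, sample sets are
#' concatenated over the union of variant keys; a sample absent from the
#' file carrying a variant is recorded missing at it.
#'
#' @param vcfPaths character vector of VCF paths (plain or bgzipped).
#' @param pedPath 6-column PED path (family, individual, father, mother,
#'   sex 1/2, phenotype 1/2).
#' @param minAdFraction minimum alternate-depth fraction in `[0, 1]`
#'   (0 disables the filter; 0.25 is the stringent setting).
#' @param genderPolicy one of `"none"`, `"skip_family"`,
#'   `"replace_sibling"`; see [applyGenderPolicy()].
#' @param dropEmpty drop variants with zero carriers after filtering.
#' @return list with `cohort` ([FamilyCohort-class]) and `presence`
#'   ([PresenceMatrix-class]); rows are ordered PED samples (retained
#'   families only), columns are in genomic order.
#' @export
ingestCohort <- function(vcfPaths, pedPath, minAdFraction = 0,
                         genderPolicy = c("none", "skip_family",
                                          "replace_sibling"),
                         dropEmpty = TRUE) {
  genderPolicy <- match.arg(genderPolicy)
  stopifnot(minAdFraction >= 0, minAdFraction <= 1)
  cohort <- cohortFromPed(readPed(pedPath))

  parsed <- lapply(vcfPaths, parseVcfPresence,
                   minAdFraction = minAdFraction)
  allVars <- unique(do.call(rbind, lapply(parsed, `[[`, "variants")))
  ord <- order(factor(allVars$chrom, levels = unique(allVars$chrom)),
               allVars$pos, allVars$ref, allVars$alt)
  allVars <- allVars[ord, ]
  allSamples <- unlist(lapply(parsed, function(p) rownames(p$presence)))
  if (anyDuplicated(allSamples))
    stop("sample(s) appear in more than one VCF: ",
         paste(unique(allSamples[duplicated(allSamples)]), collapse = ", "))

  pedSamples <- sampleInfo(cohort)$sample_id
  absent <- setdiff(pedSamples, allSamples)
  if (length(absent))
    stop("PED sample(s) missing from VCF input: ",
         paste(absent, collapse = ", "))

  nS <- length(pedSamples); nV <- nrow(allVars)
  P <- matrix(FALSE, nS, nV, dimnames = list(pedSamples, allVars$id))
  M <- matrix(TRUE, nS, nV, dimnames = list(pedSamples, allVars$id))
  for (p in parsed) {
    rows <- intersect(rownames(p$presence), pedSamples)
    if (!length(rows)) next
    cols <- colnames(p$presence)  # variant ids of this file
    P[rows, cols] <- p$presence[rows, cols]
    M[rows, cols] <- p$missing[rows, cols]
  }

  cohort <- applyGenderPolicy(cohort, genderPolicy)
  keepSamples <- sampleInfo(cohort)$sample_id
  P <- P[keepSamples, , drop = FALSE]
  M <- M[keepSamples, , drop = FALSE]
  if (dropEmpty) {
    keep <- colSums(P) > 0L
    P <- P[, keep, drop = FALSE]
    M <- M[, keep, drop = FALSE]
    allVars <- allVars[keep, , drop = FALSE]
  }
  rownames(allVars) <- NULL
  pm <- new("PresenceMatrix", presence = P, missing = M,
            variants = data.frame(id = allVars$id, chrom = allVars$chrom,
                                  pos = allVars$pos, ref = allVars$ref,
                                  alt = allVars$alt,
                                  chrom_class = chromClass(allVars$chrom),
                                  stringsAsFactors = FALSE),
            adThreshold = minAdFraction)
  list(cohort = cohort, presence = pm)
}

#' Apply a gender-mismatch policy to a cohort
#'
#' A gender mismatch is a sibling whose sex differs from the proband's.
#' Because case ascertainment is strongly male-biased while sibling
#' controls are not, mismatched sibships inflate spurious sex-chromosome
#' association. `"skip_family"` drops mismatched families;
#' `"replace_sibling"` keeps them but designates the same-sex parent as the
#' family's control; `"none"` leaves the sibling as the control designate.
#'
#' @param cohort a [FamilyCohort-class].
#' @param policy `"none"`, `"skip_family"` or `"replace_sibling"`.
#' @return the adjusted cohort (family count unchanged under
#'   `replace_sibling`; reduced by the mismatch count under `skip_family`).
#' @export
applyGenderPolicy <- function(cohort,
                              policy = c("none", "skip_family",
                                         "replace_sibling")) {
  policy <- match.arg(policy)
  fam <- families(cohort)
  mismatch <- fam$proband_sex != fam$sibling_sex
  if (policy == "skip_family") {
    fam <- fam[!mismatch, , drop = FALSE]
    smp <- sampleInfo(cohort)
    smp <- smp[smp$family_id %in% fam$family_id, , drop = FALSE]
    rownames(fam) <- rownames(smp) <- NULL
    return(new("FamilyCohort", families = fam, samples = smp))
  }
  if (policy == "replace_sibling") {
    fam$control_designate_id <- ifelse(
      mismatch,
      ifelse(fam$proband_sex == "M", fam$father_id, fam$mother_id),
      fam$sibling_id)
  } else {
    fam$control_designate_id <- fam$sibling_id
  }
  new("FamilyCohort", families = fam, samples = sampleInfo(cohort))
}

#' Case/control labels and weights for association testing or prediction
#'
#' `screen` mode contrasts one case (the proband) against one control (the
#' family's control designate) per family, unweighted. `predict` mode
#' labels probands positive and every other family member negative, with
#' per-sample weights inversely proportional to class frequency and
#' normalized so the two classes carry equal total weight.
#'
#' @param cohort a [FamilyCohort-class] (gender policy already applied).
#' @param mode `"screen"` or `"predict"`.
#' @return data.frame with `sample_id`, `label` (1 case / 0 control) and
#'   `weight`.
#' @export
associationLabels <- function(cohort, mode = c("screen", "predict")) {
  mode <- match.arg(mode)
  fam <- families(cohort)
  if (mode == "screen") {
    out <- data.frame(
      sample_id = c(fam$proband_id, fam$control_designate_id),
      label = rep(c(1L, 0L), each = nrow(fam)),
      weight = 1)
  } else {
    smp <- sampleInfo(cohort)
    label <- as.integer(smp$sample_id %in% fam$proband_id)
    nPos <- sum(label == 1L); nNeg <- sum(label == 0L)
    n <- nPos + nNeg
    weight <- ifelse(label == 1L, n / (2 * nPos), n / (2 * nNeg))
    out <- data.frame(sample_id = smp$sample_id, label = label,
                      weight = weight)
  }
  rownames(out) <- NULL
  out
}
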