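#' Configuration for a synthetic cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: three sample groups (healthy, adenoma, carcinoma) with age and
#' gender covariates; 50-bp reads assembled as insert + 3' adapter (+ random
#' filler) of mixed provenance (human small RNA, human genome, diet miRNA,
#' bacterial, junk); negative-binomial per-feature small RNA counts with
#' group-dependent log2 fold changes on selected miRNAs; per-sample species
#' proportions with group-dependent shifts on selected species; and DNA
#' taxonomic profiles equal to the true species proportions perturbed by
#' multiplicative log-normal noise.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param reads_per_sample reads generated per sample.
#' @param provenance named fractions (human_srna, human_genome, diet,
#'   bacterial, junk) summing to 1.
#' @param read_length raw read length (bp).
#' @param adapter 3' adapter sequence (default: the 21-nt Illumina small RNA
#'   3' adapter).
#' @param mirna_frac_of_srna fraction of human-sRNA reads drawn from miRNA
#'   arms (the rest from sncRNAs).
#' @param mirna_base_mean,feature_log_sd log-normal location/spread of
#'   per-feature baseline negative-binomial means.
#' @param dispersion negative-binomial dispersion of per-feature counts.
#' @param mirna_effects,sncrna_effects data.frame (`feature`, `group`,
#'   `log2fc`) of injected group effects, or NULL for defaults derived from
#'   the bundle.
#' @param species_effects data.frame (`species`, `group`, `log2fc`) of
#'   group shifts on species proportions (species referenced by name), or
#'   NULL for defaults.
#' @param species_concentration Dirichlet concentration controlling
#'   sample-to-sample variability of species proportions.
#' @param dna_noise_sigma standard deviation (log scale) of the multiplicative
#'   noise applied to true species proportions to produce DNA profiles; 0
#'   makes the DNA profile equal the truth exactly.
#' @param classifiable_frac fraction of bacterial inserts of length >= 31 nt
#'   (classifiable by the k-mer engine).
#' @param bsrna_insert_frac fraction of bacterial inserts drawn from bsRNA
#'   annotation footprints (transcript-like) rather than uniformly from the
#'   genome, so annotation count matrices are populated.
#' @param bacterial_long_length,bacterial_short_length insert length ranges
#'   for classifiable / short bacterial reads.
#' @param genome_insert_length,junk_insert_length,sncrna_insert_length insert
#'   length ranges for host-genome, junk, and sncRNA reads. All insert
#'   lengths are kept >= 20 nt so chance matches against the 100-kb host
#'   decoy are negligible and provenance classes stay well defined.
#' @param age_ranges named list of min/max ages per group.
#' @return A named list of cohort parameters.
#' @export
cohortConfig <- function(group_sizes = c(healthy = 8L, adenoma = 8L, carcinoma = 8L),
                         reads_per_sample = 20000L,
                         provenance = c(human_srna = 0.4, human_genome = 0.2,
                                        diet = 0.0, bacterial = 0.3, junk = 0.1),
                         read_length = 50L,
                         adapter = "AGATCGGAAGAGCACACGTCT",
                         mirna_frac_of_srna = 0.6,
                         mirna_base_mean = 200,
                         feature_log_sd = 1,
                         dispersion = 0.2,
                         mirna_effects = NULL,
                         sncrna_effects = NULL,
                         species_effects = NULL,
                         species_concentration = 50,
                         dna_noise_sigma = 0.3,
                         classifiable_frac = 0.85,
                         bsrna_insert_frac = 0.35,
                         bacterial_long_length = c(31L, 45L),
                         bacterial_short_length = c(20L, 30L),
                         genome_insert_length = c(32L, 46L),
                         junk_insert_length = c(26L, 45L),
                         sncrna_insert_length = c(20L, 35L),
                         age_ranges = list(healthy = c(35, 70),
                                           adenoma = c(40, 80),
                                           carcinoma = c(45, 85))) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$provenance) - 1) > 1e-9)
    stop("provenance fractions must sum to 1")
  if (!all(names(cfg$provenance) == c("human_srna", "human_genome", "diet",
                                      "bacterial", "junk")))
    stop("provenance must be named human_srna, human_genome, diet, bacterial, junk")
  cfg
}

#' Mature miRNA feature names implied by a bundle
#'
#' Arm-annotated precursors yield `<id>-5p` / `<id>-3p` features
#' (knowledge-based quantification); precursors without arm annotations yield
#' `<id>_5p-Novel` / `<id>_3p-Novel` (position-based quantification).
#'
#' @param bundle a [ReferenceBundle-class].
#' @return Character vector of mature feature names (sorted).
#' @export
mirnaFeatureNames <- function(bundle) {
  arms <- bundle@arms
  annotated <- !is.na(arms$arm5_start)
  sort(c(paste0(rep(arms$precursor_id[annotated], each = 2), c("-5p", "-3p")),
         paste0(rep(arms$precursor_id[!annotated], each = 2),
                c("_5p-Novel", "_3p-Novel"))))
}

.defaultMirnaEffects <- function(bundle) {
  arms <- bundle@arms
  ann <- arms$precursor_id[!is.na(arms$arm5_start)]
  f <- paste0(ann[seq_len(min(6, length(ann)))], "-5p")
  data.frame(
    feature = c(f[1], f[2], f[3], f[4], f[5], f[5], f[6]),
    group = c("carcinoma", "carcinoma", "carcinoma", "adenoma",
              "adenoma", "carcinoma", "carcinoma"),
    log2fc = c(2, 2, -2, 1.5, 1, 2, -1.5),
    stringsAsFactors = FALSE)
}

.defaultSncrnaEffects <- function(bundle) {
  ids <- names(bundle@sncrnas)
  data.frame(feature = ids[1:2], group = c("carcinoma", "carcinoma"),
             log2fc = c(1.5, -1.5), stringsAsFactors = FALSE)
}

.defaultSpeciesEffects <- function(bundle) {
  tax <- bundle@taxonomy
  sp <- tax$name[tax$rank == "species"]
  ef <- data.frame(species = sp[1], group = "carcinoma", log2fc = 2,
                   stringsAsFactors = FALSE)
  if (length(sp) >= 2)
    ef <- rbind(ef, data.frame(species = sp[2], group = "carcinoma",
                               log2fc = -1.5, stringsAsFactors = FALSE))
  if (length(sp) >= 3)
    ef <- rbind(ef, data.frame(species = sp[3], group = "adenoma",
                               log2fc = 1, stringsAsFactors = FALSE))
  ef
}

# effect lookup: named multiplier vector for one group over `features`
.effectMultiplier <- function(features, effects, group) {
  mult <- setNames(rep(1, length(features)), features)
  if (is.null(effects) || !nrow(effects)) return(mult)
  sel <- effects$group == group & effects$feature %in% features
  if (any(sel)) mult[effects$feature[sel]] <- 2^effects$log2fc[sel]
  mult
}

# draw inserts for miRNA features of one sample; returns list(seq, source)
.mirnaInserts <- function(bundle, counts) {
  arms <- bundle@arms
  pre <- as.character(bundle@precursors)
  plen <- setNames(nchar(pre), names(pre))
  out_seq <- character(0); out_src <- character(0)
  nz <- counts[counts > 0]
  for (f in names(nz)) {
    n <- nz[[f]]
    if (grepl("-Novel$", f)) {
      id <- sub("_(5p|3p)-Novel$", "", f)
      L <- plen[[id]]
      len <- sample(20:24, n, replace = TRUE)
      if (grepl("_5p-Novel$", f)) {
        # midpoint strictly inside the 5' half
        start <- vapply(len, function(l)
          sample.int(max(1L, floor(L / 2) - l + 1L), 1L), integer(1))
      } else {
        start <- vapply(len, function(l)
          as.integer(ceiling(L / 2)) + sample.int(L - l - as.integer(ceiling(L / 2)) + 1L, 1L),
          integer(1))
      }
      seqs <- substring(pre[[id]], start, start + len - 1L)
    } else {
      id <- sub("-(5p|3p)$", "", f)
      a <- arms[arms$precursor_id == id, ]
      iv <- if (grepl("-5p$", f)) c(a$arm5_start, a$arm5_end) else
                                  c(a$arm3_start, a$arm3_end)
      alen <- iv[2] - iv[1]
      len <- sample(20:min(24, alen), n, replace = TRUE)
      off <- vapply(len, function(l) sample.int(alen - l + 1L, 1L) - 1L, integer(1))
      seqs <- substring(pre[[id]], iv[1] + off + 1L, iv[1] + off + len)
    }
    out_seq <- c(out_seq, seqs)
    out_src <- c(out_src, rep(f, n))
  }
  list(seq = out_seq, source = out_src)
}

.sncrnaInserts <- function(bundle, counts, lenRange) {
  snc <- as.character(bundle@sncrnas)
  out_seq <- character(0); out_src <- character(0)
  nz <- counts[counts > 0]
  for (f in names(nz)) {
    n <- nz[[f]]
    L <- nchar(snc[[f]])
    len <- sample(lenRange[1]:min(lenRange[2], L), n, replace = TRUE)
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), integer(1))
    out_seq <- c(out_seq, substring(snc[[f]], start, start + len - 1L))
    out_src <- c(out_src, rep(f, n))
  }
  list(seq = out_seq, source = out_src)
}

#' Generate a synthetic cohort with full ground truth
#'
#' Deterministic for fixed `(bundle, config, seed)`. Each read is an insert
#' from its provenance source followed by the 3' adapter and random filler,
#' truncated to the read length; miRNA-arm inserts are 20-24 nt; a
#' configurable fraction of bacterial inserts are >= 31 nt (classifiable);
#' host-genome inserts avoid the embedded small RNA loci; DNA profiles are
#' the true species proportions under multiplicative log-normal noise,
#' renormalized to percent. The truth tables record every read's class and
#' source feature.
#'
#' @param bundle a [ReferenceBundle-class].
#' @param config see [cohortConfig()].
#' @param seed integer RNG seed.
#' @return A list of class `fecoduo_cohort`: `metadata` (sample_id, group,
#'   age, gender), `reads` (per-sample data.frames with read_id/seq/qual),
#'   `dnaProfiles` (species-by-sample percent matrix), and `truth`
#'   (per-read classes and sources, true species proportions, realized
#'   per-feature read counts, injected effects).
#' @seealso [writeCohort()] for on-disk serialization.
#' @export
generateCohort <- function(bundle, config = cohortConfig(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  if (abs(sum(cfg$provenance) - 1) > 1e-9) stop("provenance fractions must sum to 1")

  if (is.null(cfg$mirna_effects)) cfg$mirna_effects <- .defaultMirnaEffects(bundle)
  if (is.null(cfg$sncrna_effects)) cfg$sncrna_effects <- .defaultSncrnaEffects(bundle)
  if (is.null(cfg$species_effects)) cfg$species_effects <- .defaultSpeciesEffects(bundle)

  tax <- bundle@taxonomy
  spId <- tax$taxon_id[tax$rank == "species"]
  spName <- setNames(tax$name[tax$rank == "species"], spId)
  genomes <- as.character(bundle@genomes)
  host <- as.character(bundle@hostGenome)
  glen <- nchar(host)

  # cumulative coverage of embedded sRNA loci for O(1) overlap tests
  cov <- integer(glen)
  loci <- bundle@hostFeatureLoci
  for (i in seq_len(nrow(loci))) cov[(loci$start[i] + 1L):loci$end[i]] <- 1L
  covsum <- c(0L, cumsum(cov))

  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ns <- length(groups)
  samples <- sprintf("S%02d", seq_len(ns))
  meta <- data.frame(
    sample_id = samples, group = groups,
    age = round(vapply(groups, function(g)
      runif(1, cfg$age_ranges[[g]][1], cfg$age_ranges[[g]][2]), numeric(1)), 1),
    gender = sample(c("M", "F"), ns, replace = TRUE),
    stringsAsFactors = FALSE)

  mirFeat <- mirnaFeatureNames(bundle)
  sncFeat <- names(bundle@sncrnas)
  mirMean <- setNames(exp(rnorm(length(mirFeat), log(cfg$mirna_base_mean),
                                cfg$feature_log_sd)), mirFeat)
  sncMean <- setNames(exp(rnorm(length(sncFeat), log(cfg$mirna_base_mean),
                                cfg$feature_log_sd)), sncFeat)
  spBase <- setNames(rgamma(length(spId), shape = 2, rate = 1) + 0.05, spId)
  spBase <- spBase / sum(spBase)

  readsList <- vector("list", ns); names(readsList) <- samples
  truthList <- vector("list", ns); names(truthList) <- samples
  spTrue <- matrix(0, length(spId), ns,
                   dimnames = list(unname(spName[spId]), samples))
  dnaProf <- spTrue
  mirTruth <- matrix(0L, length(mirFeat), ns, dimnames = list(mirFeat, samples))
  sncTruth <- matrix(0L, length(sncFeat), ns, dimnames = list(sncFeat, samples))

  adapter <- cfg$adapter
  rl <- cfg$read_length

  for (j in seq_len(ns)) {
    g <- groups[j]
    nclass <- drop(rmultinom(1, cfg$reads_per_sample, cfg$provenance))
    names(nclass) <- names(cfg$provenance)

    # --- species proportions (group-shifted, Dirichlet-perturbed)
    wsp <- spBase * unname(.effectMultiplier(spName[spId], cfg$species_effects, g))
    wsp <- wsp / sum(wsp)
    p <- rgamma(length(wsp), shape = cfg$species_concentration * wsp, rate = 1)
    if (sum(p) == 0) p <- wsp
    p <- p / sum(p)
    spTrue[, j] <- p
    noise <- if (cfg$dna_noise_sigma > 0)
      exp(rnorm(length(p), 0, cfg$dna_noise_sigma)) else rep(1, length(p))
    d <- p * noise
    dnaProf[, j] <- 100 * d / sum(d)

    # --- human sRNA reads
    n_mir <- rbinom(1, nclass[["human_srna"]], cfg$mirna_frac_of_srna)
    n_snc <- nclass[["human_srna"]] - n_mir
    wm <- rnbinom(length(mirFeat),
                  mu = mirMean * .effectMultiplier(mirFeat, cfg$mirna_effects, g),
                  size = 1 / cfg$dispersion)
    if (sum(wm) == 0) wm <- rep(1, length(mirFeat))
    cm <- drop(rmultinom(1, n_mir, wm)); names(cm) <- mirFeat
    mirTruth[, j] <- cm
    mi <- .mirnaInserts(bundle, cm)

    ws <- rnbinom(length(sncFeat),
                  mu = sncMean * .effectMultiplier(sncFeat, cfg$sncrna_effects, g),
                  size = 1 / cfg$dispersion)
    if (sum(ws) == 0) ws <- rep(1, length(sncFeat))
    cs <- drop(rmultinom(1, n_snc, ws)); names(cs) <- sncFeat
    sncTruth[, j] <- cs
    si <- .sncrnaInserts(bundle, cs, cfg$sncrna_insert_length)

    # --- host genome reads, avoiding embedded sRNA loci
    ng <- nclass[["human_genome"]]
    glens <- sample(cfg$genome_insert_length[1]:cfg$genome_insert_length[2],
                    ng, replace = TRUE)
    gstart <- integer(ng)
    if (ng) {
      todo <- seq_len(ng)
      while (length(todo)) {
        cand <- vapply(glens[todo], function(l)
          sample.int(glen - l + 1L, 1L), integer(1))
        ok <- (covsum[cand + glens[todo]] - covsum[cand]) == 0L
        gstart[todo[ok]] <- cand[ok]
        todo <- todo[!ok]
      }
    }
    gseq <- substring(host, gstart, gstart + glens - 1L)
    grc <- as.logical(rbinom(ng, 1, 0.5))
    gseq[grc] <- revComp(gseq[grc])

    # --- diet reads
    nd <- nclass[["diet"]]
    dpick <- if (nd) sample(names(bundle@dietMirnas), nd, replace = TRUE) else character()
    dseq <- if (nd) as.character(bundle@dietMirnas)[dpick] else character()

    # --- bacterial reads: a configurable fraction comes from bsRNA
    # annotation footprints (transcript-like), the rest uniformly from the
    # genome; both stay substrings of a single species' genome
    nb <- nclass[["bacterial"]]
    bspecies <- if (nb) sample(spId, nb, replace = TRUE, prob = p) else character()
    long <- as.logical(rbinom(nb, 1, cfg$classifiable_frac))
    blen <- integer(nb)
    blen[long] <- sample(cfg$bacterial_long_length[1]:cfg$bacterial_long_length[2],
                         sum(long), replace = TRUE)
    blen[!long] <- sample(cfg$bacterial_short_length[1]:cfg$bacterial_short_length[2],
                          sum(!long), replace = TRUE)
    ann <- bundle@bsrnaAnnotations
    fromAnn <- as.logical(rbinom(nb, 1, cfg$bsrna_insert_frac)) &
      bspecies %in% ann$species_id
    bseq <- character(nb)
    for (i in which(fromAnn)) {
      aseq <- ann$sequence[ann$species_id == bspecies[i]]
      aseq <- aseq[sample.int(length(aseq), 1L)]
      l <- min(blen[i], nchar(aseq))
      st <- sample.int(nchar(aseq) - l + 1L, 1L)
      bseq[i] <- substr(aseq, st, st + l - 1L)
    }
    for (i in which(!fromAnn)) {
      st <- sample.int(nchar(genomes[[bspecies[i]]]) - blen[i] + 1L, 1L)
      bseq[i] <- substr(genomes[[bspecies[i]]], st, st + blen[i] - 1L)
    }
    brc <- !fromAnn & as.logical(rbinom(nb, 1, 0.5))
    bseq[brc] <- revComp(bseq[brc])

    # --- junk reads
    nj <- nclass[["junk"]]
    jseq <- .randSeqs(sample(cfg$junk_insert_length[1]:cfg$junk_insert_length[2],
                             nj, replace = TRUE))

    inserts <- c(mi$seq, si$seq, gseq, dseq, bseq, jseq)
    classes <- c(rep("human_srna", length(mi$seq) + length(si$seq)),
                 rep("human_genome", ng), rep("diet", nd),
                 rep("bacterial", nb), rep("junk", nj))
    sources <- c(mi$source, si$source, rep(NA_character_, ng), dpick,
                 bspecies, rep(NA_character_, nj))

    # assemble 50-bp reads: insert + adapter + random filler, truncated
    ilen <- nchar(inserts)
    fill <- pmax(0L, rl - ilen - nchar(adapter))
    reads <- substr(paste0(inserts, adapter, .randSeqs(fill)), 1L, rl)

    ord <- sample.int(length(reads))
    ids <- sprintf("%s_R%06d", samples[j], seq_along(reads))
    readsList[[j]] <- data.frame(
      read_id = ids, seq = reads[ord],
      qual = strrep("I", nchar(reads[ord])),
      stringsAsFactors = FALSE)
    truthList[[j]] <- data.frame(
      read_id = ids, class = classes[ord], source = sources[ord],
      insert_length = ilen[ord], stringsAsFactors = FALSE)
  }

  structure(list(
    metadata = meta,
    reads = readsList,
    dnaProfiles = dnaProf,
    truth = list(classes = truthList,
                 speciesProportions = spTrue,
                 mirnaCounts = mirTruth,
                 sncrnaCounts = sncTruth,
                 mirnaEffects = cfg$mirna_effects,
                 sncrnaEffects = cfg$sncrna_effects,
                 speciesEffects = cfg$species_effects),
    config = cfg), class = "fecoduo_cohort")
}

#' Serialize a cohort to disk
#'
#' Writes per-sample FASTQ files, the sample metadata TSV, per-sample DNA
#' taxonomic profiles in mpa text format, and the per-read truth tables.
#'
#' @param cohort a `fecoduo_cohort` from [generateCohort()].
#' @param dir output directory.
#' @param bundle the [ReferenceBundle-class] the cohort was generated from
#'   (needed to expand species abundances into full mpa lineages).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, bundle) {
  dir.create(file.path(dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dna_mpa"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(cohort$reads)) {
    writeFastq(cohort$reads[[s]], file.path(dir, "fastq", paste0(s, ".fastq")))
    mpa <- mpaFromSpeciesAbundance(cohort$dnaProfiles[, s], bundle@taxonomy)
    writeMpaTable(mpa, file.path(dir, "dna_mpa", paste0(s, ".mpa")))
    write.table(cohort$truth$classes[[s]],
                file.path(dir, "truth", paste0(s, "_reads.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(species = rownames(cohort$truth$speciesProportions),
                         cohort$truth$speciesProportions,
                         check.names = FALSE),
              file.path(dir, "truth", "species_proportions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
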