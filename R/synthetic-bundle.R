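#' Configuration for a synthetic reference bundle
#'
#' Defaults are a reduced-scale emulation of the reference sets the triage
#' pipeline assumes: miRNA precursor hairpins (a configurable fraction with
#' annotated 5p/3p arms), sncRNAs shorter than 80 nt with biotypes, a
#' single-contig host genome decoy with the small RNA loci embedded in it,
#' dietary miRNAs, divergent microbial genomes under a rooted seven-rank
#' taxonomy, and bacterial sRNA annotations extracted from the genomes.
#'
#' @param n_precursors number of miRNA precursor hairpins.
#' @param precursor_length min/max hairpin length (nt).
#' @param arm_annotated_frac fraction of precursors carrying both 5p and 3p
#'   arm annotations; the rest carry none and are quantified position-based.
#' @param arm_length mature arm length (nt).
#' @param n_sncrnas number of human sncRNA annotations.
#' @param sncrna_length min/max sncRNA length (nt, below 80).
#' @param sncrna_biotypes named probability vector of biotypes.
#' @param host_genome_length host decoy contig length (bp).
#' @param n_diet_mirnas number of diet-derived miRNAs (20-24 nt).
#' @param n_species number of microbial species.
#' @param genome_length per-species genome length (bp).
#' @param sibling_pair if TRUE, species 2 is generated as a mutated copy of
#'   species 1 so the two share a controlled fraction of 31-mers.
#' @param sibling_shared_kmer_frac target shared 31-mer fraction for the
#'   sibling pair.
#' @param n_bsrna_per_species bacterial sRNA annotations extracted per species.
#' @param bsrna_length min/max bsRNA length (nt; kept strictly below 80 so the
#'   nonredundant-set length filter retains them).
#' @param n_shared_bsrna number of bsRNA sequences annotated identically to two
#'   distinct species (exercises nonredundant collapsing).
#' @return A named list of bundle parameters.
#' @export
bundleConfig <- function(n_precursors = 60L,
                         precursor_length = c(70L, 90L),
                         arm_annotated_frac = 0.7,
                         arm_length = 22L,
                         n_sncrnas = 40L,
                         sncrna_length = c(30L, 79L),
                         sncrna_biotypes = c(tRNA = 0.45, piRNA = 0.3,
                                             snoRNA = 0.15, snRNA = 0.1),
                         host_genome_length = 100000L,
                         n_diet_mirnas = 30L,
                         n_species = 6L,
                         genome_length = 30000L,
                         sibling_pair = FALSE,
                         sibling_shared_kmer_frac = 0.5,
                         n_bsrna_per_species = 8L,
                         bsrna_length = c(40L, 79L),
                         n_shared_bsrna = 2L) {
  as.list(environment())
}

# rooted taxonomy: kingdom > phylum > class > order > family > genus > species;
# species are paired into genera so genus-level LCA cases exist
.buildTaxonomy <- function(n_species) {
  stopifnot(n_species >= 1)
  n_genera <- ceiling(n_species / 2)
  n_branch <- min(2L, n_genera) # phylum..family branches actually used
  df <- data.frame(taxon_id = "k1", name = "Bacteria", rank = "kingdom",
                   parent_id = "k1", stringsAsFactors = FALSE)
  for (b in seq_len(n_branch)) {
    letter <- LETTERS[b]
    df <- rbind(df, data.frame(
      taxon_id = paste0(c("p", "c", "o", "f"), b),
      name = paste0(c("Phylum_", "Class_", "Order_", "Family_"), letter),
      rank = c("phylum", "class", "order", "family"),
      parent_id = c("k1", paste0(c("p", "c", "o"), b)),
      stringsAsFactors = FALSE))
  }
  for (g in seq_len(n_genera)) {
    fam <- paste0("f", (g - 1L) %% n_branch + 1L)
    df <- rbind(df, data.frame(
      taxon_id = paste0("g", g),
      name = sprintf("Genus_%02d", g), rank = "genus",
      parent_id = fam, stringsAsFactors = FALSE))
  }
  for (s in seq_len(n_species)) {
    df <- rbind(df, data.frame(
      taxon_id = paste0("s", s),
      name = sprintf("Species_%02d", s), rank = "species",
      parent_id = paste0("g", ceiling(s / 2)), stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  df
}

# substitute a different base every `spacing` positions
.mutateEvery <- function(seq, spacing) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- strsplit(seq, "")[[1]]
  idx <- seq(1L, length(chars), by = spacing)
  chars[idx] <- swap[chars[idx]]
  paste(chars, collapse = "")
}

# place sequences at non-overlapping random positions in `genome`, replacing
# the resident bases; returns list(genome, loci) with 0-based half-open loci
.embedFeatures <- function(genome, seqs, types) {
  glen <- nchar(genome)
  loci <- data.frame(id = character(), type = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(seqs)) {
    len <- nchar(seqs[[i]])
    for (try in 1:200) {
      p <- sample.int(glen - len + 1L, 1L) # 1-based start
      ok <- !nrow(taken) || all(p + len - 1 < taken[, 1] | p > taken[, 2])
      if (ok) break
      if (try == 200) stop("could not place features without overlap")
    }
    substr(genome, p, p + len - 1L) <- seqs[[i]]
    taken <- rbind(taken, c(p, p + len - 1L))
    loci <- rbind(loci, data.frame(id = names(seqs)[i], type = types[i],
                                   start = p - 1L, end = p + len - 1L,
                                   stringsAsFactors = FALSE))
  }
  list(genome = genome, loci = loci)
}

#' Generate a synthetic reference bundle
#'
#' Deterministic for a fixed `(config, seed)` pair. The host genome embeds
#' every precursor and sncRNA sequence (so reads from those loci would also
#' align to the genome and triage order is exercised), species genomes are
#' pairwise divergent in 31-mer space unless a sibling pair with controlled
#' overlap is requested, and at least `n_shared_bsrna` bsRNA sequences are
#' annotated identically to two distinct species.
#'
#' @param config see [bundleConfig()].
#' @param seed integer RNG seed.
#' @return A [ReferenceBundle-class].
#' @examples
#' bundle <- generateReferenceBundle(bundleConfig(n_species = 3L), seed = 7)
#' bundle
#' @export
generateReferenceBundle <- function(config = bundleConfig(), seed = 1L) {
  set.seed(seed)
  cfg <- config

  # precursors and arm annotations
  plens <- sample(cfg$precursor_length[1]:cfg$precursor_length[2],
                  cfg$n_precursors, replace = TRUE)
  pre <- .randSeqs(plens)
  names(pre) <- sprintf("pre%04d", seq_len(cfg$n_precursors))
  n_annot <- round(cfg$arm_annotated_frac * cfg$n_precursors)
  annotated <- sort(sample.int(cfg$n_precursors, n_annot))
  arms <- data.frame(precursor_id = names(pre),
                     arm5_start = NA_integer_, arm5_end = NA_integer_,
                     arm3_start = NA_integer_, arm3_end = NA_integer_,
                     stringsAsFactors = FALSE)
  if (n_annot) {
    s5 <- sample(5:9, n_annot, replace = TRUE)
    off3 <- sample(5:9, n_annot, replace = TRUE)
    arms$arm5_start[annotated] <- s5
    arms$arm5_end[annotated] <- s5 + cfg$arm_length
    arms$arm3_end[annotated] <- plens[annotated] - off3
    arms$arm3_start[annotated] <- plens[annotated] - off3 - cfg$arm_length
  }

  # sncRNAs
  slens <- sample(cfg$sncrna_length[1]:cfg$sncrna_length[2],
                  cfg$n_sncrnas, replace = TRUE)
  snc <- .randSeqs(slens)
  names(snc) <- sprintf("snc%04d", seq_len(cfg$n_sncrnas))
  biotype <- setNames(
    sample(names(cfg$sncrna_biotypes), cfg$n_sncrnas, replace = TRUE,
           prob = cfg$sncrna_biotypes),
    names(snc))

  # diet miRNAs
  diet <- .randSeqs(sample(20:24, cfg$n_diet_mirnas, replace = TRUE))
  names(diet) <- sprintf("diet%04d", seq_len(cfg$n_diet_mirnas))

  # host genome with embedded small RNA loci
  host <- .randSeq(cfg$host_genome_length)
  emb <- .embedFeatures(host, c(pre, snc),
                        c(rep("precursor", length(pre)),
                          rep("sncrna", length(snc))))
  host <- emb$genome

  # taxonomy and species genomes
  tax <- .buildTaxonomy(cfg$n_species)
  genomes <- .randSeqs(rep(cfg$genome_length, cfg$n_species))
  names(genomes) <- paste0("s", seq_len(cfg$n_species))
  if (isTRUE(cfg$sibling_pair) && cfg$n_species >= 2) {
    spacing <- max(32L, round(31 / (1 - cfg$sibling_shared_kmer_frac)))
    genomes[2] <- .mutateEvery(genomes[[1]], spacing)
  }

  # shared bsRNA sequences: donor species 1, distinct recipients
  shared <- data.frame(annotation_id = character(), species_id = character(),
                       sequence = character(), stringsAsFactors = FALSE)
  n_shared <- min(cfg$n_shared_bsrna,
                  max(0L, cfg$n_species - 1L))
  for (i in seq_len(n_shared)) {
    len <- sample(cfg$bsrna_length[1]:cfg$bsrna_length[2], 1L)
    p <- sample.int(cfg$genome_length - len + 1L, 1L)
    s <- substr(genomes[[1]], p, p + len - 1L)
    recip <- i + 1L
    q <- sample.int(cfg$genome_length - len + 1L, 1L)
    substr(genomes[[recip]], q, q + len - 1L) <- s
    shared <- rbind(shared,
      data.frame(annotation_id = sprintf("bsr_s%d_shared%02d", 1L, i),
                 species_id = "s1", sequence = s, stringsAsFactors = FALSE),
      data.frame(annotation_id = sprintf("bsr_s%d_shared%02d", recip, i),
                 species_id = paste0("s", recip), sequence = s,
                 stringsAsFactors = FALSE))
  }

  # per-species bsRNA annotations (substrings of the final genomes)
  ann <- list(shared)
  for (sp in seq_len(cfg$n_species)) {
    lens <- sample(cfg$bsrna_length[1]:cfg$bsrna_length[2],
                   cfg$n_bsrna_per_species, replace = TRUE)
    starts <- vapply(lens, function(l)
      sample.int(cfg$genome_length - l + 1L, 1L), integer(1))
    ann[[sp + 1L]] <- data.frame(
      annotation_id = sprintf("bsr_s%d_%03d", sp, seq_along(lens)),
      species_id = paste0("s", sp),
      sequence = substring(genomes[[sp]], starts, starts + lens - 1L),
      stringsAsFactors = FALSE)
  }
  bsrna <- do.call(rbind, ann)
  rownames(bsrna) <- NULL

  methods::new("ReferenceBundle",
    precursors = Biostrings::DNAStringSet(pre),
    arms = arms,
    sncrnas = Biostrings::DNAStringSet(snc),
    sncrnaBiotype = biotype,
    hostGenome = Biostrings::DNAString(host),
    hostFeatureLoci = emb$loci,
    dietMirnas = Biostrings::DNAStringSet(diet),
    genomes = Biostrings::DNAStringSet(genomes),
    taxonomy = tax,
    bsrnaAnnotations = bsrna)
}

#' Serialize / load a reference bundle as FASTA + TSV files
#'
#' @param bundle a [ReferenceBundle-class].
#' @param dir output directory (created if missing).
#' @return `writeBundle` returns `dir` invisibly; `readBundle` returns the
#'   reconstructed [ReferenceBundle-class].
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeFasta(as.character(bundle@precursors), file.path(dir, "precursors.fa"))
  .writeFasta(as.character(bundle@sncrnas), file.path(dir, "sncrnas.fa"))
  .writeFasta(setNames(as.character(bundle@hostGenome), "host"),
              file.path(dir, "host_genome.fa"))
  .writeFasta(as.character(bundle@dietMirnas), file.path(dir, "diet_mirnas.fa"))
  .writeFasta(as.character(bundle@genomes), file.path(dir, "genomes.fa"))
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(bundle@arms, "arms.tsv")
  wt(data.frame(id = names(bundle@sncrnaBiotype),
                biotype = unname(bundle@sncrnaBiotype)), "sncrna_biotypes.tsv")
  wt(bundle@hostFeatureLoci, "host_feature_loci.tsv")
  wt(bundle@taxonomy, "taxonomy.tsv")
  wt(bundle@bsrnaAnnotations, "bsrna_annotations.tsv")
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  rt <- function(f) read.table(file.path(dir, f), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  bio <- rt("sncrna_biotypes.tsv")
  methods::new("ReferenceBundle",
    precursors = .readFasta(file.path(dir, "precursors.fa")),
    arms = rt("arms.tsv"),
    sncrnas = .readFasta(file.path(dir, "sncrnas.fa")),
    sncrnaBiotype = setNames(bio$biotype, bio$id),
    hostGenome = .readFasta(file.path(dir, "host_genome.fa"))[[1L]],
    hostFeatureLoci = rt("host_feature_loci.tsv"),
    dietMirnas = .readFasta(file.path(dir, "diet_mirnas.fa")),
    genomes = .readFasta(file.path(dir, "genomes.fa")),
    taxonomy = rt("taxonomy.tsv"),
    bsrnaAnnotations = rt("bsrna_annotations.tsv"))
}
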