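# Synthetic genome, expression, homology and sRNA generators with planted
# ground truth.  Layout is rejection-free sequential placement of independent
# "units" along one chromosome, with inter-unit spacing wide enough that no
# planted transcript can pair with a foreign gene and no geometry decision
# falls within class_margin_bp of the classifier window boundary.

# latent log-scale condition-effect correlation that yields a target
# FPKM-scale (2^x) Pearson correlation, by inverting the bivariate
# log-normal correlation corr = (exp(cov_ln) - 1) / (exp(var_ln) - 1);
# capped at 1 where replicate noise makes the target unreachable
latent_rho <- function(rho, cond_sd, noise_sd) {
  if (rho <= 0) return(rho)
  ln2sq <- log(2)^2
  var_ln <- (cond_sd^2 + noise_sd^2) * ln2sq
  if (var_ln == 0) return(rho)
  cov_ln <- log(1 + rho * (exp(var_ln) - 1))
  min(1, cov_ln / (ln2sq * cond_sd^2))
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults define the standard simulated study: 50 coding genes, 10 planted
#' lncRNAs per class (overlapping / divergent / convergent NATs, lincRNAs,
#' incRNAs), 9 conditions x 3 replicates plus a two-fraction assay, planted
#' within-pair correlation 0.8 for overlapping-NAT pairs and 0 elsewhere, a
#' 3 log2-unit planted fraction enrichment, and replicate noise of 0.2 log2
#' units around condition effects of sd 1 log2 unit.
#'
#' @param n_coding_genes Number of coding genes (hosts for planted NATs and
#'   incRNAs are drawn from these; must be >= 4 * `n_per_lnc_class`).
#' @param n_per_lnc_class Planted lncRNAs per class.
#' @param n_decoys Intergenic coding-potential decoy transcripts (strong
#'   homology hits and long ORFs, planted to be removed by the coding filter).
#' @param n_cc_pairs Extra coding-gene pairs planted per coding-coding
#'   geometry (overlapping, divergent, convergent), for pair-category
#'   comparisons.
#' @param chrom,chrom_length Chromosome name and length (bp); generation
#'   fails if the layout does not fit.
#' @param pairing_window_bp Divergent/convergent pairing window; must match
#'   the classifier's `window_bp`.
#' @param class_margin_bp Safety margin kept clear of the window boundary.
#' @param n_conditions,n_replicates Condition-profile design.
#' @param rho_nco Planted correlation of condition effects within
#'   overlapping-NAT/sense-gene pairs.
#' @param rho_other Planted correlation for every other pair type.
#' @param enrichment_log2fc Planted mean log2 difference between the two
#'   fraction groups for enriched features.
#' @param n_enriched Number of lncRNAs planted as enriched in the first
#'   fraction (capped at the number of planted lncRNAs).
#' @param noise_sd Replicate noise sd, log2 units.
#' @param cond_sd Condition-effect sd, log2 units.
#' @param base_log2_fpkm,base_sd Mean and sd of per-feature baseline
#'   log2 FPKM.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_coding_genes = 50, n_per_lnc_class = 10,
                             n_decoys = 0, n_cc_pairs = 0,
                             chrom = "chrSim", chrom_length = 3e6,
                             pairing_window_bp = 1000, class_margin_bp = 100,
                             n_conditions = 9, n_replicates = 3,
                             rho_nco = 0.8, rho_other = 0,
                             enrichment_log2fc = 3, n_enriched = 10,
                             noise_sd = 0.2, cond_sd = 1,
                             base_log2_fpkm = 4, base_sd = 1, seed = 7) {
  cfg <- list(n_coding_genes = as.integer(n_coding_genes),
              n_per_lnc_class = as.integer(n_per_lnc_class),
              n_decoys = as.integer(n_decoys),
              n_cc_pairs = as.integer(n_cc_pairs),
              chrom = chrom, chrom_length = as.numeric(chrom_length),
              pairing_window_bp = as.integer(pairing_window_bp),
              class_margin_bp = as.integer(class_margin_bp),
              n_conditions = as.integer(n_conditions),
              n_replicates = as.integer(n_replicates),
              rho_nco = rho_nco, rho_other = rho_other,
              enrichment_log2fc = enrichment_log2fc,
              n_enriched = as.integer(n_enriched),
              noise_sd = noise_sd, cond_sd = cond_sd,
              base_log2_fpkm = base_log2_fpkm, base_sd = base_sd,
              seed = as.integer(seed))
  if (cfg$n_coding_genes < 1L || cfg$n_per_lnc_class < 1L ||
      cfg$n_conditions < 1L || cfg$n_replicates < 1L)
    stop("counts must be >= 1")
  if (cfg$n_decoys < 0L || cfg$n_cc_pairs < 0L || cfg$n_enriched < 0L)
    stop("counts must be non-negative")
  if (cfg$rho_nco < 0 || cfg$rho_nco > 1 || cfg$rho_other < 0 ||
      cfg$rho_other > 1)
    stop("rho must lie in [0, 1]")
  if (cfg$class_margin_bp < 1L) stop("class_margin_bp must be >= 1")
  if (cfg$pairing_window_bp <= 2L * cfg$class_margin_bp)
    stop("pairing_window_bp must exceed twice class_margin_bp")
  if (cfg$noise_sd < 0 || cfg$cond_sd < 0) stop("sd parameters must be >= 0")
  if (cfg$n_coding_genes < 4L * cfg$n_per_lnc_class)
    stop("n_coding_genes must be >= 4 * n_per_lnc_class (hosts for ",
         "overlapping/divergent/convergent NATs and incRNAs)")
  structure(cfg, class = "SyntheticConfig")
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# random sequence guaranteed to contain no ATG in any frame -> zero ORFs
noncoding_seq <- function(len) {
  s <- paste(rand_bases(len), collapse = "")
  while (grepl("ATG", s, fixed = TRUE)) s <- gsub("ATG", "ACG", s, fixed = TRUE)
  s
}

STOPS <- c("TAA", "TAG", "TGA")

# sequence whose longest ORF covers ~80% of the transcript
coding_seq <- function(len) {
  stopifnot(len >= 165L)
  orf_nt <- 3L * (floor(0.8 * len / 3) )
  utr5 <- 30L
  utr3 <- len - utr5 - orf_nt
  if (utr3 < 0L) { orf_nt <- orf_nt + utr3 %/% 3L * 3L; utr3 <- len - utr5 - orf_nt }
  all_cod <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                               c("A","C","G","T")), 1, paste, collapse = "")
  body_pool <- setdiff(all_cod, STOPS)
  n_body <- orf_nt / 3L - 2L
  paste0(noncoding_seq(utr5),
         "ATG", paste(sample(body_pool, n_body, replace = TRUE), collapse = ""),
         sample(STOPS, 1L),
         noncoding_seq(utr3))
}

# exon layout helpers: relative coordinates, shifted to >= 0 on assembly
make_exons <- function(lens, introns) {
  starts <- cumsum(c(0L, head(lens, -1L) + introns))
  data.table(start = as.integer(starts), end = as.integer(starts + lens))
}

new_unit <- function() list(tx = list(), ex = list())

add_tx <- function(unit, tx_id, gene_id, strand, exons_rel, offset,
                   class_code, role, partner = NA_character_) {
  ex <- copy(exons_rel)
  ex[, `:=`(start = start + as.integer(offset), end = end + as.integer(offset))]
  unit$tx[[length(unit$tx) + 1L]] <- data.table(
    transcript_id = tx_id, gene_id = gene_id, start = min(ex$start),
    end = max(ex$end), strand = strand, class_code = class_code,
    role = role, partner_gene_id = partner)
  ex[, `:=`(transcript_id = tx_id, strand = strand)]
  unit$ex[[length(unit$ex) + 1L]] <- ex
  unit
}

gene_exons <- function(big_intron = NA) {
  if (!is.na(big_intron)) {
    make_exons(c(400L, 400L), as.integer(big_intron))
  } else {
    n_ex <- sample(3:5, 1L)
    make_exons(sample(200:600, n_ex, replace = TRUE),
               sample(100:300, n_ex - 1L, replace = TRUE))
  }
}

lnc_exons <- function() {
  if (sample(c(TRUE, FALSE), 1L)) {
    make_exons(sample(250:600, 1L), integer(0))
  } else {
    make_exons(sample(150:300, 2L, replace = TRUE), sample(80:150, 1L))
  }
}

#' Generate a synthetic annotated genome with planted lncRNA classes
#'
#' Plants `n_per_lnc_class` transcripts of each class with unambiguous
#' geometry: overlapping NATs share >= 1 bp with their partner gene on the
#' opposite strand; divergent/convergent NATs sit head-to-head/tail-to-tail
#' with an end gap at least `class_margin_bp` inside the pairing window;
#' lincRNAs and decoys lie at least `pairing_window_bp + class_margin_bp`
#' from every gene; incRNAs lie entirely within a host-gene intron on the
#' same strand.
#'
#' @param cfg A `SyntheticConfig`.
#' @return List with `anno` (`AnnotationSet` of the assembled transcriptome,
#'   all biotypes `"unknown"`), `truth` (list of `transcripts` and `pairs`
#'   tables), and `seqs` (named character vector of transcript sequences).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_seed(cfg$seed, {
    W <- cfg$pairing_window_bp; M <- cfg$class_margin_bp
    gap_rng <- c(10L, W - M)
    npc <- cfg$n_per_lnc_class
    gid <- sprintf("G%04d", seq_len(cfg$n_coding_genes))
    host_role <- rep("free", cfg$n_coding_genes)
    host_role[seq_len(4L * npc)] <-
      rep(c("OVL", "DIV", "CONV", "INC"), each = npc)
    units <- list()
    lnc_counter <- c(OVL = 0L, DIV = 0L, CONV = 0L, INC = 0L)
    for (i in seq_len(cfg$n_coding_genes)) {
      role <- host_role[i]
      gstrand <- sample(STRANDS, 1L)
      u <- new_unit()
      if (role == "INC") {
        lnc_w <- sample(200:400, 1L)
        gex <- gene_exons(big_intron = lnc_w + 60L)
      } else {
        gex <- gene_exons()
      }
      gw <- max(gex$end)
      u <- add_tx(u, paste0(gid[i], ".1"), gid[i], gstrand, gex, 0L,
                  "=", "coding")
      if (role != "free") {
        k <- lnc_counter[role] + 1L; lnc_counter[role] <- k
        lex <- if (role == "INC") make_exons(lnc_w, integer(0)) else lnc_exons()
        lw <- max(lex$end)
        lstrand <- if (role == "INC") gstrand else setdiff(STRANDS, gstrand)
        gap <- sample(gap_rng[1L]:gap_rng[2L], 1L)
        off <- switch(role,
          OVL = gw - sample(100:min(400L, lw - 1L, gw - 1L), 1L),
          DIV = if (gstrand == "+") -(gap + lw) else gw + gap,
          CONV = if (gstrand == "+") gw + gap else -(gap + lw),
          INC = 430L)
        tx_id <- switch(role,
          OVL = sprintf("LNC_OVL_%03d", k), DIV = sprintf("LNC_DIV_%03d", k),
          CONV = sprintf("LNC_CON_%03d", k), INC = sprintf("LNC_INC_%03d", k))
        ccode <- switch(role, OVL = "x", INC = "i", "u")
        lrole <- switch(role, OVL = "NAT_OVERLAPPING", DIV = "NAT_DIVERGENT",
                        CONV = "NAT_CONVERGENT", INC = "INCRNA")
        u <- add_tx(u, tx_id, tx_id, lstrand, lex, off, ccode, lrole, gid[i])
      }
      units[[length(units) + 1L]] <- u
    }
    # coding-coding geometry pairs
    if (cfg$n_cc_pairs > 0L) {
      cc_id <- 0L
      for (geom in c("CCO", "CCD", "CCC")) for (j in seq_len(cfg$n_cc_pairs)) {
        cc_id <- cc_id + 1L
        ga <- sprintf("GP%04dA", cc_id); gb <- sprintf("GP%04dB", cc_id)
        exa <- gene_exons(); exb <- gene_exons()
        wa <- max(exa$end)
        u <- new_unit()
        if (geom == "CCO") {
          ov <- sample(100:400, 1L)
          u <- add_tx(u, paste0(ga, ".1"), ga, "+", exa, 0L, "=", "coding")
          u <- add_tx(u, paste0(gb, ".1"), gb, "-", exb, wa - ov, "=", "coding")
        } else {
          gap <- sample(gap_rng[1L]:gap_rng[2L], 1L)
          s <- if (geom == "CCD") c("-", "+") else c("+", "-")
          u <- add_tx(u, paste0(ga, ".1"), ga, s[1L], exa, 0L, "=", "coding")
          u <- add_tx(u, paste0(gb, ".1"), gb, s[2L], exb, wa + gap, "=", "coding")
        }
        units[[length(units) + 1L]] <- u
      }
    }
    # intergenic lincRNAs and coding-potential decoys
    for (k in seq_len(npc)) {
      u <- new_unit()
      tx_id <- sprintf("LNC_LIN_%03d", k)
      u <- add_tx(u, tx_id, tx_id, sample(STRANDS, 1L), lnc_exons(), 0L,
                  "u", "LINCRNA")
      units[[length(units) + 1L]] <- u
    }
    for (k in seq_len(cfg$n_decoys)) {
      u <- new_unit()
      tx_id <- sprintf("DECOY_%03d", k)
      u <- add_tx(u, tx_id, tx_id, sample(STRANDS, 1L),
                  make_exons(sample(500:800, 1L), integer(0)), 0L,
                  "u", "decoy")
      units[[length(units) + 1L]] <- u
    }
    # shuffle unit order, then lay out left to right with a clearance gap
    units <- units[sample(length(units))]
    gap_unit <- W + M + 100L
    cursor <- 1000L
    tx_all <- list(); ex_all <- list()
    for (u in units) {
      tx <- rbindlist(u$tx); ex <- rbindlist(u$ex)
      shift <- as.integer(cursor - min(ex$start))
      tx[, `:=`(start = start + shift, end = end + shift)]
      ex[, `:=`(start = start + shift, end = end + shift)]
      cursor <- max(ex$end) + gap_unit
      tx_all[[length(tx_all) + 1L]] <- tx
      ex_all[[length(ex_all) + 1L]] <- ex
    }
    if (cursor > cfg$chrom_length)
      stop("chrom_length too small for requested configuration (needs >= ",
           cursor, " bp)")
    tx <- rbindlist(tx_all); ex <- rbindlist(ex_all)
    tx[, chrom := cfg$chrom]; ex[, chrom := cfg$chrom]
    anno <- annotation_set(
      tx[, list(transcript_id, gene_id, chrom, start, end, strand,
                class_code, biotype = "unknown")],
      ex[, list(transcript_id, chrom, start, end, strand)])
    lens <- transcript_lengths(anno)
    truth_tx <- tx[, list(transcript_id, gene_id, role, partner_gene_id)]
    # nearest gene (span gap, ties by gene_id) recorded for lincRNAs
    genes <- gene_spans(subset_annotation(anno,
               truth_tx[role == "coding", transcript_id]))
    linc <- truth_tx[role == "LINCRNA", transcript_id]
    for (id in linc) {
      r <- anno$transcripts[transcript_id == id]
      gap <- pmax(genes$start - r$end, r$start - genes$end, 0L)
      best <- order(gap, genes$gene_id)[1L]
      truth_tx[transcript_id == id, partner_gene_id := genes$gene_id[best]]
    }
    setkey(truth_tx, transcript_id)
    # enrichment plant: first n_enriched lncRNAs in id order
    lnc_ids <- sort(truth_tx[grepl("^LNC_", transcript_id), transcript_id])
    enr <- head(lnc_ids, cfg$n_enriched)
    truth_tx[, enriched := ifelse(transcript_id %in% enr, "fraction_a", "none")]
    # pair table with planted correlations
    g2tx <- setNames(tx[role == "coding", transcript_id],
                     tx[role == "coding", gene_id])
    pr <- truth_tx[role %in% c("NAT_OVERLAPPING", "NAT_DIVERGENT",
                               "NAT_CONVERGENT", "LINCRNA"),
                   list(a_feature = transcript_id,
                        b_gene = partner_gene_id,
                        pair_type = c(NAT_OVERLAPPING = "NCO",
                                      NAT_DIVERGENT = "NCD",
                                      NAT_CONVERGENT = "NCC",
                                      LINCRNA = "LC")[role])]
    cc <- tx[grepl("^GP", gene_id) & endsWith(gene_id, "A"),
             list(a_feature = transcript_id, b_gene = sub("A$", "B", gene_id))]
    if (nrow(cc)) {
      # cc units were built CCO then CCD then CCC in ascending pair id order
      cc <- cc[order(a_feature)]
      cc[, pair_type := rep(c("CCO", "CCD", "CCC"), each = cfg$n_cc_pairs)]
      pr <- rbind(pr, cc)
    }
    pr[, b_feature := g2tx[b_gene]]
    pr[, rho := ifelse(pair_type == "NCO", cfg$rho_nco, cfg$rho_other)]
    seqs <- vapply(anno$transcripts$transcript_id, function(id) {
      r <- truth_tx[id, role]
      if (r %in% c("coding", "decoy")) coding_seq(lens[[id]])
      else noncoding_seq(lens[[id]])
    }, character(1L))
    list(anno = anno,
         truth = list(transcripts = truth_tx[], pairs = pr[]),
         seqs = seqs)
  })
}

#' Reference coding annotation from a synthetic genome
#'
#' @param gen Result of [generate_annotation()].
#' @return `AnnotationSet` of the coding transcripts with biotype `"coding"`.
#' @export
coding_reference <- function(gen) {
  ids <- gen$truth$transcripts[role == "coding", transcript_id]
  ref <- subset_annotation(gen$anno, ids)
  ref$transcripts[, biotype := "coding"]
  ref
}

#' Generate a planted-structure FPKM expression table
#'
#' Log-normal model: per feature a baseline log2 FPKM, additive condition
#' effects (correlated within planted pairs), a fraction effect of
#' `enrichment_log2fc` log2 units for planted enriched features, and i.i.d.
#' replicate noise.  FPKM = 2^(log2 value), so all values are strictly
#' positive.  The pair's `rho` is planted on the FPKM scale — the scale on
#' which pair correlations are later computed: the latent correlation of the
#' log-scale condition effects is calibrated by inverting the bivariate
#' log-normal correlation formula, so that the population Pearson
#' correlation of the two FPKM vectors equals `rho` (capped where replicate
#' noise makes a target unreachable, e.g. rho = 1 with noise_sd > 0).
#' Condition samples carry fraction label `"total"`; the fraction assay
#' contributes `n_replicates` samples each of `"fraction_a"` and
#' `"fraction_b"` without condition effects.
#'
#' @param truth Truth tables from [generate_annotation()].
#' @param cfg The same `SyntheticConfig`.
#' @return An `ExpressionTable` over all transcripts.
#' @export
generate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  tt <- truth$transcripts
  if (!nrow(tt)) stop("empty truth table")
  if (nrow(truth$pairs) &&
      !all(c(truth$pairs$a_feature, truth$pairs$b_feature) %in%
           tt$transcript_id))
    stop("truth/config mismatch: pair features missing from truth table")
  with_seed(cfg$seed + 1L, {
    feats <- sort(tt$transcript_id)
    nf <- length(feats); nc <- cfg$n_conditions; nr <- cfg$n_replicates
    mu <- setNames(rnorm(nf, cfg$base_log2_fpkm, cfg$base_sd), feats)
    E <- matrix(rnorm(nf * nc, 0, cfg$cond_sd), nf, nc,
                dimnames = list(feats, NULL))
    for (i in seq_len(nrow(truth$pairs))) {
      p <- truth$pairs[i]
      if (p$rho > 0 && p$a_feature %in% feats && p$b_feature %in% feats) {
        rl <- latent_rho(p$rho, cfg$cond_sd, cfg$noise_sd)
        E[p$b_feature, ] <- rl * E[p$a_feature, ] +
          sqrt(1 - rl^2) * E[p$b_feature, ]
      }
    }
    conds <- sprintf("cond_%02d", seq_len(nc))
    cond_samples <- data.table(
      sample_id = sprintf("%s_r%d", rep(conds, each = nr),
                          rep(seq_len(nr), nc)),
      condition = rep(conds, each = nr),
      timepoint = rep(seq_len(nc), each = nr),
      fraction = "total", replicate = rep(seq_len(nr), nc))
    frac_samples <- data.table(
      sample_id = c(sprintf("fraction_a_r%d", seq_len(nr)),
                    sprintf("fraction_b_r%d", seq_len(nr))),
      condition = "fraction_assay",
      timepoint = 0L,
      fraction = rep(c("fraction_a", "fraction_b"), each = nr),
      replicate = rep(seq_len(nr), 2L))
    sheet <- rbind(cond_samples, frac_samples)
    L <- matrix(0, nf, nrow(sheet), dimnames = list(feats, sheet$sample_id))
    L <- L + mu
    cond_idx <- match(sheet$condition, conds)   # NA for fraction samples
    for (j in seq_len(nrow(sheet)))
      if (!is.na(cond_idx[j])) L[, j] <- L[, j] + E[, cond_idx[j]]
    shift <- cfg$enrichment_log2fc / 2
    enr <- tt[enriched == "fraction_a", transcript_id]
    L[enr, sheet$fraction == "fraction_a"] <-
      L[enr, sheet$fraction == "fraction_a"] + shift
    L[enr, sheet$fraction == "fraction_b"] <-
      L[enr, sheet$fraction == "fraction_b"] - shift
    L <- L + matrix(rnorm(length(L), 0, cfg$noise_sd), nrow(L), ncol(L))
    expression_table(2^L, sheet)
  })
}

#' Generate protein-homology hits with planted coding decoys
#'
#' Coding transcripts and decoys each receive one hit passing all criteria
#' (e-value < 1e-4, alignment >= 40 aa, identity >= 35, coverage >= 35);
#' planted lncRNAs receive either no hit or a hit failing at least one
#' criterion.
#'
#' @param truth Truth tables from [generate_annotation()].
#' @param cfg The same `SyntheticConfig`.
#' @return `data.table` of homology hits (see [read_homology_hits()]).
#' @export
generate_homology_hits <- function(truth, cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  tt <- truth$transcripts
  with_seed(cfg$seed + 2L, {
    rows <- list()
    strong <- function(id) data.table(
      query_id = id, subject_id = sprintf("SP_%05d", sample.int(99999L, 1L)),
      aln_len_aa = sample(60:200, 1L),
      pct_identity = round(runif(1L, 40, 90), 1),
      query_cov_pct = round(runif(1L, 50, 95), 1),
      subject_cov_pct = round(runif(1L, 50, 95), 1),
      evalue = 10^-sample(10:50, 1L))
    weak <- function(id) {
      fail <- sample(c("aln", "ident", "cov", "evalue"), 1L)
      data.table(
        query_id = id, subject_id = sprintf("SP_%05d", sample.int(99999L, 1L)),
        aln_len_aa = if (fail == "aln") sample(5:39, 1L) else sample(40:80, 1L),
        pct_identity = if (fail == "ident") round(runif(1L, 10, 34.9), 1)
                       else round(runif(1L, 35, 60), 1),
        query_cov_pct = if (fail == "cov") round(runif(1L, 1, 34.9), 1)
                        else round(runif(1L, 35, 60), 1),
        subject_cov_pct = if (fail == "cov") round(runif(1L, 1, 34.9), 1)
                          else 0,
        evalue = if (fail == "evalue") 10^runif(1L, -3.9, 0) else 1e-10)
    }
    for (i in seq_len(nrow(tt))) {
      id <- tt$transcript_id[i]; role <- tt$role[i]
      if (role %in% c("coding", "decoy")) rows[[length(rows) + 1L]] <- strong(id)
      else if (runif(1L) < 0.5) rows[[length(rows) + 1L]] <- weak(id)
    }
    if (!length(rows))
      return(data.table(query_id = character(0), subject_id = character(0),
                        aln_len_aa = integer(0), pct_identity = numeric(0),
                        query_cov_pct = numeric(0),
                        subject_cov_pct = numeric(0), evalue = numeric(0)))
    rbindlist(rows)
  })
}

#' Generate sRNA region counts with or without planted secondary siRNAs
#'
#' Negative case: all reads fall inside the amiRNA target window of the
#' chosen transcript.  Positive case: `spread_fraction` of the reads are
#' distributed over the transcript body outside the window, emulating
#' secondary-siRNA production.
#'
#' @param truth,cfg Truth tables and config from [generate_annotation()].
#' @param anno The generated `AnnotationSet` (for coordinates).
#' @param transcript_id Target transcript (default: first overlapping NAT).
#' @param case `"negative"` or `"positive"`.
#' @param spread_fraction Fraction of reads outside the window (positive case).
#' @param n_reads Total reads on the transcript.
#' @param total_mapped Library size for RPM normalization.
#' @return List with `counts`, `total_mapped`, `transcript_id`, `target_site`.
#' @export
generate_srna_counts <- function(truth, cfg, anno, transcript_id = NULL,
                                 case = c("negative", "positive"),
                                 spread_fraction = 0.5, n_reads = 1000L,
                                 total_mapped = 1e6) {
  case <- match.arg(case)
  tt <- truth$transcripts
  if (is.null(transcript_id)) {
    cand <- sort(tt[role == "NAT_OVERLAPPING", transcript_id])
    if (!length(cand)) stop("no overlapping NAT to target")
    transcript_id <- cand[1L]
  }
  tid <- transcript_id
  tx <- anno$transcripts[tid, on = "transcript_id"]
  if (is.na(tx$start)) stop("unknown transcript: ", transcript_id)
  mid <- as.integer((tx$start + tx$end) %/% 2L)
  site <- genomic_interval(tx$chrom, mid - 10L, mid + 11L, tx$strand)
  counts <- data.table(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       count = integer(0))
  if (n_reads > 0L) {
    n_out <- if (case == "positive") as.integer(round(n_reads * spread_fraction))
             else 0L
    n_in <- as.integer(n_reads) - n_out
    rows <- list(data.table(chrom = tx$chrom, start = site$start,
                            end = site$end, strand = tx$strand, count = n_in))
    if (n_out > 0L) {
      # bins on the transcript span, clear of the site +/- 60 bp
      bins <- seq(tx$start, tx$end - 21L, by = 100L)
      bins <- bins[bins + 21L <= site$start - 60L | bins >= site$end + 60L]
      if (!length(bins)) stop("transcript too short to spread reads outside site")
      per <- diff(round(seq(0L, n_out, length.out = length(bins) + 1L)))
      keep <- per > 0L
      rows[[2L]] <- data.table(chrom = tx$chrom, start = as.integer(bins[keep]),
                               end = as.integer(bins[keep] + 21L),
                               strand = tx$strand, count = as.integer(per[keep]))
    }
    counts <- rbindlist(rows)[count > 0L]
  }
  list(counts = counts[order(start)], total_mapped = as.integer(total_mapped),
       transcript_id = transcript_id, target_site = site)
}

#' Write a complete synthetic input bundle to disk
#'
#' Produces every input the pipeline reads (assembled GTF with class codes,
#' reference coding GTF, transcript FASTA, FPKM matrix + sample sheet,
#' homology hits, sRNA counts for a negative and a positive case) plus the
#' machine-readable truth tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scale `"default"` (the standard simulated study) or `"tiny"`.
#' @param cfg Optional explicit `SyntheticConfig` overriding `scale`.
#' @return List with `paths` (named file paths), `cfg`, `truth`.
#' @export
make_fixtures <- function(out_dir, seed = 7, scale = c("default", "tiny"),
                          cfg = NULL) {
  scale <- match.arg(scale)
  if (is.null(cfg)) {
    cfg <- if (scale == "tiny")
      synthetic_config(n_coding_genes = 12, n_per_lnc_class = 3, n_decoys = 2,
                       n_cc_pairs = 2, n_enriched = 3, chrom_length = 5e5,
                       seed = seed)
    else
      synthetic_config(n_decoys = 10, n_cc_pairs = 5, seed = seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_annotation(cfg)
  expr <- generate_expression(gen$truth, cfg)
  hits <- generate_homology_hits(gen$truth, cfg)
  srna_neg <- generate_srna_counts(gen$truth, cfg, gen$anno, case = "negative")
  srna_pos <- generate_srna_counts(gen$truth, cfg, gen$anno, case = "positive")
  p <- function(f) file.path(out_dir, f)
  paths <- c(annotation = p("annotation.gtf"), reference = p("reference.gtf"),
             seqs = p("transcripts.fa"), expression = p("expression.tsv"),
             samples = p("samples.tsv"), hits = p("hits.tsv"),
             srna_negative = p("srna_negative.tsv"),
             srna_positive = p("srna_positive.tsv"),
             truth = p("truth.tsv"), truth_pairs = p("truth_pairs.tsv"),
             config = p("config.json"))
  write_annotation(gen$anno, paths[["annotation"]])
  write_annotation(coding_reference(gen), paths[["reference"]])
  write_transcript_seqs(gen$seqs, paths[["seqs"]])
  write_expression_table(expr, paths[["expression"]], paths[["samples"]])
  write_homology_hits(hits, paths[["hits"]])
  write_srna_counts(srna_neg$counts, srna_neg$total_mapped,
                    paths[["srna_negative"]])
  write_srna_counts(srna_pos$counts, srna_pos$total_mapped,
                    paths[["srna_positive"]])
  fwrite(gen$truth$transcripts, paths[["truth"]], sep = "\t")
  fwrite(gen$truth$pairs, paths[["truth_pairs"]], sep = "\t")
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  list(paths = as.list(paths), cfg = cfg, truth = gen$truth)
}
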