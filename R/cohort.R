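#' Configuration for the synthetic multi-donor FMT cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a pool of
#' stool donors each contributing one or more donation samples, FMT
#' recipients treated with a multi-donor batch, placebo recipients, and a
#' strain universe in which within-lineage distances are far smaller than
#' between-lineage distances (the bimodal normalised-distance picture that
#' motivates a strain-match threshold).
#'
#' @param n_donors Number of FMT donors.
#' @param donor_samples_range Integer interval: donation samples per donor.
#' @param n_fmt_recipients,n_placebo_recipients Recipient counts; each
#'   recipient has a baseline and one post-intervention sample.
#' @param pool_size_range Integer interval: donors per FMT batch. A
#'   degenerate interval (e.g. `c(4, 4)`) gives fixed-size pools.
#' @param n_species Number of profiled species.
#' @param species_prevalence Probability that a subject carries a given
#'   species (controls strains per sample). Either a scalar or a named
#'   vector `c(donor = ..., recipient = ...)`; the default gives healthy
#'   donors a richer strain complement than the (dysbiotic) recipients.
#' @param bacteroides_prevalence Carriage probability of the *Bacteroides*
#'   index species for every subject. Kept high (near-ubiquitous in the
#'   human gut) so the Prevotella/Bacteroides ratio is defined for almost
#'   all samples.
#' @param marker_length Length (bp) of each species' concatenated marker
#'   alignment.
#' @param d_intra Expected per-site substitution probability between two
#'   samples of the same strain lineage.
#' @param d_inter Expected per-site substitution probability between a
#'   lineage and the species root (between-lineage pairs differ at roughly
#'   twice this rate). Must exceed `d_intra`.
#' @param n_lineages_per_species Optional cap on distinct lineages per
#'   species; `NULL` (default) lets every carrying subject found its own
#'   lineage unless background sharing fires.
#' @param p_shared_lineage Probability that a subject reuses another
#'   subject's lineage for a species (background strain sharing between
#'   unrelated subjects).
#' @param donor_efficiency Probability that a donor-carried species strain
#'   engrafts in a true recipient; scalar or vector of length `n_donors`.
#' @param detection_rate Probability that a carried species strain is
#'   profiled in a sample: a function of read count, or a constant in
#'   `[0, 1]`. The default is logistic in log10 read count, ~0.9 at typical
#'   depths, emulating depth-dependent strain dropout.
#' @param read_depth_range Reads-per-sample interval (log-uniform draw).
#' @param include_donor_batch Also emit pooled donor-batch samples (these
#'   are excluded from all pairwise analyses and are off by default).
#' @param unknown_fraction_range Interval for the per-sample unknown
#'   (unclassified) fraction of the taxonomic profile.
#' @param genes_per_sample Mean number of annotated genes per sample in the
#'   COG table.
#' @param seed Integer master seed; fans out to per-stream child seeds.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_donors = 9,
                          donor_samples_range = c(1L, 3L),
                          n_fmt_recipients = 24,
                          n_placebo_recipients = 12,
                          pool_size_range = c(4L, 4L),
                          n_species = 36,
                          species_prevalence = c(donor = 0.26,
                                                 recipient = 0.10),
                          bacteroides_prevalence = 0.60,
                          marker_length = 1000,
                          d_intra = 5e-4,
                          d_inter = 0.02,
                          n_lineages_per_species = NULL,
                          p_shared_lineage = 0.01,
                          donor_efficiency = 0.30,
                          detection_rate = NULL,
                          read_depth_range = c(1e6, 1e7),
                          include_donor_batch = FALSE,
                          unknown_fraction_range = c(0.1, 0.3),
                          genes_per_sample = 150,
                          seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              donor_samples_range = as.integer(donor_samples_range),
              n_fmt_recipients = as.integer(n_fmt_recipients),
              n_placebo_recipients = as.integer(n_placebo_recipients),
              pool_size_range = as.integer(pool_size_range),
              n_species = as.integer(n_species),
              species_prevalence = species_prevalence,
              bacteroides_prevalence = bacteroides_prevalence,
              marker_length = as.integer(marker_length),
              d_intra = d_intra, d_inter = d_inter,
              n_lineages_per_species = n_lineages_per_species,
              p_shared_lineage = p_shared_lineage,
              donor_efficiency = donor_efficiency,
              detection_rate = detection_rate,
              read_depth_range = read_depth_range,
              include_donor_batch = isTRUE(include_donor_batch),
              unknown_fraction_range = unknown_fraction_range,
              genes_per_sample = genes_per_sample,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("configuration error: ", msg,
                                             call. = FALSE)
  chk(cfg$n_donors >= 1, "n_donors must be >= 1")
  chk(cfg$marker_length > 0, "marker_length must be > 0")
  chk(length(cfg$pool_size_range) == 2 &&
        cfg$pool_size_range[1] <= cfg$pool_size_range[2],
      "pool_size_range must be a nondecreasing interval")
  chk(cfg$pool_size_range[2] <= cfg$n_donors,
      "pool_size_range exceeds n_donors")
  chk(cfg$d_intra < cfg$d_inter, "d_intra must be < d_inter")
  sp <- cfg$species_prevalence
  if (length(sp) == 1L) sp <- c(donor = unname(sp), recipient = unname(sp))
  chk(length(sp) == 2L && all(c("donor", "recipient") %in% names(sp)),
      "species_prevalence must be scalar or c(donor=, recipient=)")
  cfg$species_prevalence <- sp
  probs <- c(cfg$species_prevalence, cfg$bacteroides_prevalence,
             cfg$p_shared_lineage, cfg$d_intra,
             cfg$d_inter, cfg$donor_efficiency)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  eff <- cfg$donor_efficiency
  chk(length(eff) %in% c(1L, cfg$n_donors),
      "donor_efficiency must be scalar or one value per donor")
  if (length(eff) == 1L) cfg$donor_efficiency <- rep(eff, cfg$n_donors)
  if (is.null(cfg$detection_rate)) {
    mid <- sqrt(prod(cfg$read_depth_range))
    cfg$detection_rate <- local({
      mid <- mid
      function(read_count) {
        stats::plogis(stats::qlogis(0.9) + log10(read_count) - log10(mid))
      }
    })
  } else if (is.numeric(cfg$detection_rate)) {
    p <- cfg$detection_rate
    chk(p >= 0 && p <= 1, "constant detection_rate must lie in [0, 1]")
    cfg$detection_rate <- local({p <- p; function(read_count) p})
  }
  chk(is.function(cfg$detection_rate), "detection_rate must be a function or constant")
  structure(cfg, class = "cohort_config")
}

# mutate integer-coded sequence: each site substituted with prob `rate`
# to one of the three other bases.
mutate_seq <- function(x, rate) {
  hit <- which(runif(length(x)) < rate)
  if (length(hit) > 0) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- ((x[hit] - 1L + shift) %% 4L) + 1L
  }
  x
}

decode_dna <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

# sample() treats a length-1 vector as 1:x; guard degenerate intervals
draw_from <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

#' Generate a synthetic multi-donor FMT cohort with ground truth
#'
#' Produces every input the downstream analysis consumes — sample roster,
#' per-species strain alignments, species relative-abundance table, COG
#' annotation table, reference pairings — together with a truth set of the
#' simulated engraftment events. Post-intervention sequences of an FMT
#' recipient derive from a donor lineage (plus intra-lineage noise) exactly
#' for the species in the truth set's engraftment events, and from the
#' recipient's own baseline lineage otherwise; placebo recipients always
#' retain their baseline lineages. Output is deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `fmt_cohort`: list with `roster`,
#'   `alignments`, `abundance`, `cog`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 9)

  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  fmt <- sprintf("R%02d", seq_len(cfg$n_fmt_recipients))
  plc <- sprintf("P%02d", seq_len(cfg$n_placebo_recipients))
  subjects <- c(donors, fmt, plc)
  species <- species_names(cfg$n_species)

  # --- roster & read depths -------------------------------------------------
  roster <- with_seed(seeds[1], {
    n_dsamp <- draw_from(seq(cfg$donor_samples_range[1],
                             cfg$donor_samples_range[2]), cfg$n_donors)
    rows <- list(
      tibble::tibble(
        sample_id = as.character(unlist(mapply(
          function(d, k) sprintf("%s-S%d", d, seq_len(k)),
          donors, n_dsamp, SIMPLIFY = FALSE), use.names = FALSE)),
        subject_id = rep(donors, n_dsamp),
        role = "donor", timepoint = "donation"),
      tibble::tibble(
        sample_id = c(rbind(paste0(fmt, "-BL"), paste0(fmt, "-WK"))),
        subject_id = rep(fmt, each = 2),
        role = "fmt_recipient",
        timepoint = rep(c("baseline", "post"), cfg$n_fmt_recipients)),
      tibble::tibble(
        sample_id = c(rbind(paste0(plc, "-BL"), paste0(plc, "-WK"))),
        subject_id = rep(plc, each = 2),
        role = "placebo_recipient",
        timepoint = rep(c("baseline", "post"), cfg$n_placebo_recipients))
    )
    if (cfg$include_donor_batch) {
      rows <- c(rows, list(tibble::tibble(
        sample_id = "BATCH-S1", subject_id = "BATCH",
        role = "donor_batch", timepoint = "donation")))
    }
    r <- dplyr::bind_rows(rows)
    lo <- log10(cfg$read_depth_range[1]); hi <- log10(cfg$read_depth_range[2])
    r$read_count <- as.integer(round(10 ^ runif(nrow(r), lo, hi)))
    r
  })

  # --- donor pools ----------------------------------------------------------
  pools <- with_seed(seeds[2], {
    sizes <- draw_from(seq(cfg$pool_size_range[1], cfg$pool_size_range[2]),
                       cfg$n_fmt_recipients)
    stats::setNames(lapply(sizes, function(k) sort(sample(donors, k))), fmt)
  })

  # --- species carriage -----------------------------------------------------
  carriage <- with_seed(seeds[3], {
    prev_subj <- ifelse(subjects %in% donors,
                        cfg$species_prevalence[["donor"]],
                        cfg$species_prevalence[["recipient"]])
    p <- outer(prev_subj, rep(1, cfg$n_species))
    p[, grepl("^Bacteroides", species)] <- cfg$bacteroides_prevalence
    matrix(runif(length(subjects) * cfg$n_species) < p,
           nrow = length(subjects), dimnames = list(subjects, species))
  })

  # --- lineage assignment ---------------------------------------------------
  lineage <- with_seed(seeds[4], {
    m <- matrix(NA_integer_, length(subjects), cfg$n_species,
                dimnames = list(subjects, species))
    for (s in species) {
      carriers <- subjects[carriage[, s]]
      n_new <- 0L
      for (subj in carriers) {
        assigned <- m[carriers, s]
        assigned <- assigned[!is.na(assigned)]
        cap_hit <- !is.null(cfg$n_lineages_per_species) &&
          n_new >= cfg$n_lineages_per_species
        if ((length(assigned) > 0 && runif(1) < cfg$p_shared_lineage) ||
            (cap_hit && length(assigned) > 0)) {
          m[subj, s] <- sample(assigned, 1)
        } else {
          n_new <- n_new + 1L
          m[subj, s] <- n_new
        }
      }
    }
    m
  })

  # --- engraftment events ---------------------------------------------------
  eff <- cfg$donor_efficiency
  if (length(eff) == 1L) eff <- rep(eff, cfg$n_donors)
  names(eff) <- donors
  # per (recipient, species) at most one donor strain becomes dominant;
  # each pool donor's marginal engraftment probability equals its
  # configured efficiency (renormalised only when the pool's combined
  # probability would exceed one)
  events <- with_seed(seeds[5], {
    out <- list()
    for (r in fmt) {
      for (s in species) {
        cand <- pools[[r]][carriage[pools[[r]], s]]
        if (length(cand) == 0) next
        p <- eff[cand]
        if (sum(p) > 1) p <- p / sum(p)
        winner_idx <- findInterval(runif(1), cumsum(c(0, p)))
        if (winner_idx > length(cand)) next  # no engraftment
        out[[length(out) + 1L]] <- tibble::tibble(
          donor = cand[winner_idx], recipient = r, species = s)
      }
    }
    dplyr::bind_rows(out) %||% tibble::tibble(donor = character(),
                                              recipient = character(),
                                              species = character())
  })
  if (nrow(events) == 0) {
    events <- tibble::tibble(donor = character(), recipient = character(),
                             species = character())
  }

  # --- per-sample species sets and source lineages --------------------------
  # each entry: sample -> named integer vector species -> lineage id owner is
  # encoded as (subject, lineage id) pairs; we store the owning subject so a
  # sequence is drawn from that subject's lineage ancestor.
  sample_species <- sample_lineage_owners(roster, carriage, events, species)

  # --- sequences ------------------------------------------------------------
  alignments <- with_seed(seeds[6], {
    al <- list()
    for (s in species) {
      root <- sample.int(4L, cfg$marker_length, replace = TRUE)
      owners <- unique(stats::na.omit(lineage[, s]))
      lin_seqs <- lapply(owners, function(l) mutate_seq(root, cfg$d_inter))
      names(lin_seqs) <- as.character(owners)
      recs <- character(0)
      for (smp in roster$sample_id) {
        own <- sample_species[[smp]]
        if (!s %in% names(own)) next
        lin <- lineage[own[[s]], s]
        recs[smp] <- decode_dna(mutate_seq(lin_seqs[[as.character(lin)]],
                                           cfg$d_intra))
      }
      al[[s]] <- recs
    }
    al
  })

  # --- detection dropout ----------------------------------------------------
  depth <- stats::setNames(roster$read_count, roster$sample_id)
  alignments <- with_seed(seeds[7], {
    lapply(alignments, function(recs) {
      if (length(recs) == 0) return(recs)
      keep <- runif(length(recs)) < cfg$detection_rate(depth[names(recs)])
      recs[keep]
    })
  })

  # --- abundance table ------------------------------------------------------
  abundance <- with_seed(seeds[8], {
    rows <- lapply(roster$sample_id, function(smp) {
      present <- names(sample_species[[smp]])
      unk <- runif(1, cfg$unknown_fraction_range[1],
                   cfg$unknown_fraction_range[2])
      ab <- stats::setNames(rep(0, cfg$n_species), species)
      if (length(present) > 0) {
        w <- stats::rexp(length(present))
        ab[present] <- w / sum(w) * (1 - unk)
      } else {
        unk <- 1
      }
      tibble::as_tibble(c(list(sample_id = smp), as.list(ab),
                          list(UNKNOWN = unk)))
    })
    dplyr::bind_rows(rows)
  })

  # --- COG annotation table -------------------------------------------------
  cog <- with_seed(seeds[9], {
    cats <- cog_categories()
    prof <- lapply(subjects, function(su) {
      w <- stats::rgamma(length(cats) + 1, shape = 2)
      w / sum(w)  # last slot = unannotated
    })
    names(prof) <- subjects
    rows <- lapply(seq_len(nrow(roster)), function(i) {
      smp <- roster$sample_id[i]
      su <- roster$subject_id[i]
      p <- prof[[su]] %||% rep(1 / (length(cats) + 1), length(cats) + 1)
      n_genes <- stats::rpois(1, cfg$genes_per_sample)
      if (n_genes == 0) return(NULL)
      drawn <- sample(c(cats, NA_character_), n_genes, replace = TRUE, prob = p)
      gene_id <- sprintf("%s_g%04d", smp, seq_len(n_genes))
      extra <- which(!is.na(drawn) & runif(n_genes) < 0.05)
      out <- tibble::tibble(sample_id = smp, gene_id = gene_id,
                            category = unname(drawn))
      if (length(extra) > 0) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          sample_id = smp, gene_id = gene_id[extra],
          category = unname(vapply(drawn[extra], function(cc)
            sample(setdiff(cats, cc), 1), character(1)))))
      }
      out
    })
    dplyr::bind_rows(rows)
  })

  lineage_tbl <- tibble::as_tibble(as.data.frame.table(lineage,
                                                       stringsAsFactors = FALSE))
  names(lineage_tbl) <- c("subject", "species", "lineage")
  lineage_tbl <- lineage_tbl[!is.na(lineage_tbl$lineage), ]

  truth <- list(true_pairings = pools,
                engraftment_events = events,
                lineage_assignment = lineage_tbl)

  structure(list(roster = roster, alignments = alignments,
                 abundance = abundance, cog = cog, truth = truth,
                 config = cfg),
            class = "fmt_cohort")
}

# For each sample, which species it carries and which subject's lineage each
# species' strain derives from (engrafted species point at the donor).
sample_lineage_owners <- function(roster, carriage, events, species) {
  out <- list()
  for (i in seq_len(nrow(roster))) {
    smp <- roster$sample_id[i]
    su <- roster$subject_id[i]
    if (!su %in% rownames(carriage)) {  # donor batch pseudo-subject
      out[[smp]] <- stats::setNames(character(0), character(0))
      next
    }
    own_sp <- species[carriage[su, ]]
    owners <- stats::setNames(rep(su, length(own_sp)), own_sp)
    if (roster$role[i] == "fmt_recipient" && roster$timepoint[i] == "post") {
      ev <- events[events$recipient == su, , drop = FALSE]
      if (nrow(ev) > 0) {
        owners[ev$species] <- ev$donor  # replaces or adds
      }
    }
    out[[smp]] <- owners
  }
  out
}

species_names <- function(n) {
  base <- c(sprintf("Prevotella_sp%02d", 1:4),
            sprintf("Bacteroides_sp%02d", 1:4),
            sprintf("Clostridium_sp%02d", 1:100))
  base[seq_len(n)]
}

#' The 23 COG functional category codes
#' @return Character vector of single-letter COG category codes.
#' @export
cog_categories <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z",
    "W", "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q")
}

#' Reference pairing table of a cohort truth set
#' @param truth The `truth` element of an [generate_cohort()] result (or the
#'   cohort itself).
#' @return Long tibble with columns `recipient`, `donor`.
#' @export
true_pairings_table <- function(truth) {
  if (inherits(truth, "fmt_cohort")) truth <- truth$truth
  tp <- truth$true_pairings
  tibble::tibble(recipient = rep(names(tp), lengths(tp)),
                 donor = unlist(tp, use.names = FALSE))
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat("Synthetic FMT cohort:",
      sum(x$roster$role == "donor"), "donor samples,",
      sum(x$roster$role == "fmt_recipient"), "FMT recipient samples,",
      sum(x$roster$role == "placebo_recipient"), "placebo samples;",
      length(x$alignments), "species;",
      nrow(x$truth$engraftment_events), "engraftment events\n")
  invisible(x)
}
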