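# Seeded generators for every input the pipeline needs: PWM sets, fixture
# promoters with planted motifs and pinned reference alleles, and
# planted-effect screening datasets. All generators are pure functions of
# (seed, parameters) and restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Reported point mutations of the engineered GTH1 promoter variants
#'
#' The catalogue of single-nucleotide exchanges characterising the
#' sorting-derived GTH1 promoter variants (PGS1-PGS5, isolated by
#' error-prone PCR and cell sorting) and the reverse-engineered
#' point-mutation variants (PGMutA-PGMutU plus the MutB+MutP double
#' mutant), together with the TFBS families predicted gained or lost by
#' each variant. Positions are upstream of the start codon; notation as in
#' [parse_mutation()].
#'
#' @return Data frame with columns `type` (`"sorting"`/`"point"`),
#'   `variant`, `mutations` (comma-separated notation), `tfbs_gained`,
#'   `tfbs_lost` (comma-separated family names, `""` when none).
#' @examples
#' cat1 <- gth1_variant_catalog()
#' lengths(lapply(parse_mutations(cat1$mutations[cat1$type == "sorting"]), c))
#' @export
gth1_variant_catalog <- function() {
  data.frame(
    type = c(rep("sorting", 5L), rep("point", 11L)),
    variant = c("PGS1", "PGS2", "PGS3", "PGS4", "PGS5",
                "PGMutA", "PGMutB", "PGMutC", "PGMutD", "PGMutP", "PGMutQ",
                "PGMutR", "PGMutS", "PGMutT", "PGMutU", "PGMutBP"),
    mutations = c(
      "-453T>C,-449A>G,-445T>C,-372A>G,-340A>G,-189C>T,-151T>A",
      "-308T>G,-304T>C,-269T>A,-237G>T,-190A>G,-138A>C",
      "-379T>C,-304T>C,-235A>G,-225G>A,-167C>T",
      "-453T>C,-374T>A,-336G>A",
      "-453T>C,-442T>C,-353A>G,-347A>T,-313T>C,-291A>C,-269T>G,-169T>G",
      "-445T>C",
      "-453T>C",
      "-320G>A",
      "-322A>G",
      "-235A>G",
      "-225G>A",
      "-258T>A",
      "-251C>A",
      "-249T>G",
      "-238A>G",
      "-453T>C,-235A>G"
    ),
    tfbs_gained = c(
      "CSRE,MGCM,YMIG", "DUIS,PHD1,YCAT,YSTR", "AZF1", "CSRE",
      "CSRE,ROX1,YABF,YGAL,YMAT,YMSE",
      "CSRE,MGCM", "CSRE", "CSRE,YORE,VTBP", "CSRE", "", "MGCM",
      "MGCM,YORE", "YMCM", "GAL", "MGCM,ARPU,YORE,ASG1", "CSRE"
    ),
    tfbs_lost = c(
      "YABF", "FKHD,GATA,MGCM,PRES,YABF", "GATA,PDRE,PRES,YMIG,YQA1",
      "ASG1", "BZIP,HOMD,ICGG,MGCM,PRES,RDR1,RFXP,RRPE,TALE",
      "", "", "", "GATA,MGCM,RDR1", "MIG", "MIG,PDRE,YQA1",
      "MIG,ICGG,YMCM,RDNA", "MIG", "MIG", "MIG", "MIG"
    ),
    stringsAsFactors = FALSE
  )
}

#' Reference alleles pinned by the variant catalogue
#'
#' Every mutated position in [gth1_variant_catalog()] implies the reference
#' base at that position; the fixture promoter generator honours these so
#' that all catalogued mutation lists apply without reference mismatches.
#' The implied alleles are mutually consistent (checked).
#'
#' @return Data frame with columns `position` (upstream, negative) and
#'   `base`, one row per constrained position, sorted by position.
#' @export
gth1_reference_alleles <- function() {
  muts <- parse_mutations(gth1_variant_catalog()$mutations)
  pos <- vapply(muts, function(m) m$position, integer(1))
  ref <- vapply(muts, function(m) m$ref, character(1))
  df <- unique(data.frame(position = pos, base = ref, stringsAsFactors = FALSE))
  dup <- df$position[duplicated(df$position)]
  if (length(dup) > 0) {
    stop("gth1_reference_alleles: inconsistent alleles at ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a deterministic set of synthetic PWMs
#'
#' One matrix per requested family, each with a unique random consensus and
#' counts concentrated on the consensus base according to its information
#' level. These matrices stand in for a curated fungal TFBS library in
#' tests and examples; they are synthetic and carry no biological meaning
#' beyond their family labels.
#'
#' @param seed Integer seed.
#' @param family_codes Character vector of unique family codes; defaults to
#'   the five nutrient-responsive families recurring in the variant
#'   catalogue.
#' @param widths Integer vector of matrix widths (recycled; all >= 5).
#'   Default 10.
#' @param information_levels Fraction of each column's counts on the
#'   consensus base (recycled; in (0.25, 1\]). Default 0.9.
#' @param total_count Count total per column (default 20).
#' @param pseudocount,core_size Passed to [normalize_pwm()].
#' @return Named list of `pwm` objects (names = family codes).
#' @examples
#' pwms <- make_pwm_set(seed = 1)
#' vapply(pwms, function(p) matrix_similarity(p, p$consensus), numeric(1))
#' @export
make_pwm_set <- function(seed, family_codes = c("F$CSRE", "Y$MIG", "F$GATA",
                                                "F$MGCM", "F$PRES"),
                         widths = 10L, information_levels = 0.9,
                         total_count = 20L, pseudocount = 0.8,
                         core_size = 4L) {
  if (anyDuplicated(family_codes)) {
    stop("make_pwm_set: duplicate family codes", call. = FALSE)
  }
  n <- length(family_codes)
  widths <- rep_len(as.integer(widths), n)
  if (any(widths < 5L)) stop("make_pwm_set: widths must be >= 5", call. = FALSE)
  info <- rep_len(information_levels, n)
  if (any(info <= 0.25 | info > 1)) {
    stop("make_pwm_set: information_levels must be in (0.25, 1]", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    seen <- character()
    out <- vector("list", n)
    for (k in seq_len(n)) {
      repeat {
        cons <- sample(bases, widths[k], replace = TRUE)
        key <- paste(cons, collapse = "")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      cnt <- matrix(0, 4L, widths[k], dimnames = list(bases, NULL))
      main <- round(total_count * info[k])
      rest <- total_count - main
      for (j in seq_len(widths[k])) {
        others <- setdiff(bases, cons[j])
        split_ <- as.vector(stats::rmultinom(1, rest, rep(1 / 3, 3)))
        # consensus base must stay the strict column maximum
        while (any(split_ >= main)) {
          split_ <- as.vector(stats::rmultinom(1, rest, rep(1 / 3, 3)))
        }
        cnt[cons[j], j] <- main
        cnt[others, j] <- split_
      }
      out[[k]] <- normalize_pwm(cnt, pseudocount = pseudocount,
                                matrix_id = paste0(family_codes[k], ".01"),
                                factor_name = family_codes[k],
                                family_code = family_codes[k],
                                core_size = core_size)
    }
    names(out) <- family_codes
    out
  })
}

#' Generate a synthetic fixture promoter
#'
#' A random background sequence with (a) pinned reference alleles at the
#' positions of the catalogued variant mutations, so every catalogued
#' mutation list applies cleanly, and (b) optional planted motifs: a PWM
#' consensus embedded at a chosen position, possibly degraded by a given
#' number of mismatches (each mismatch uses the lowest-frequency base at
#' its motif position, so a single restoring substitution recreates the
#' consensus). The sequence is synthetic — only the pinned alleles tie it
#' to the real promoter's printed coordinates.
#'
#' @param seed Integer seed.
#' @param length Sequence length in nt (default 740, the canonical upstream
#'   window).
#' @param constraints Data frame with columns `position`, `base` (default
#'   [gth1_reference_alleles()]); `NULL` for none.
#' @param plantings List of plantings, each a list with `pwm`, `position`
#'   (upstream start of the motif), optional `mismatches` (default 0) and
#'   `mismatch_offsets` (1-based offsets within the motif; drawn at random
#'   when omitted).
#' @param gc GC content of the random background (default 0.5).
#' @param label Sequence label (default `"synthetic_promoter"`).
#' @return A [promoter_sequence()]; the `plantings` attribute records each
#'   planted motif (family, matrix_id, start, end, mismatch offsets and
#'   positions), the `constraints` attribute the applied allele pins.
#'   Conflicting plantings/constraints raise an error listing the
#'   offending positions.
#' @export
make_fixture_promoter <- function(seed, length = 740L,
                                  constraints = gth1_reference_alleles(),
                                  plantings = list(), gc = 0.5,
                                  label = "synthetic_promoter") {
  length <- as.integer(length)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .with_seed(seed, {
    b <- sample(bases, length, replace = TRUE, prob = probs)
    owner <- character(length)  # "" = background, else claim label
    claimed <- function(idx) owner[idx] != ""
    plant_rows <- list()
    for (k in seq_along(plantings)) {
      pl <- plantings[[k]]
      pwm <- pl$pwm
      if (!is_pwm(pwm)) stop("make_fixture_promoter: planting ", k,
                             " has no pwm", call. = FALSE)
      w <- pwm$width
      start <- as.integer(pl$position)
      if (start < -length || start + w - 1L > -1L) {
        stop("make_fixture_promoter: planting ", k, " out of bounds",
             call. = FALSE)
      }
      idx <- upstream_to_index(start, length) + 0:(w - 1L)
      if (any(claimed(idx))) {
        stop("make_fixture_promoter: planting conflict at position(s) ",
             paste(index_to_upstream(idx[claimed(idx)], length), collapse = ", "),
             call. = FALSE)
      }
      word <- pwm$consensus
      mm <- as.integer(pl$mismatches %||% 0L)
      offs <- integer()
      if (mm > 0L) {
        offs <- pl$mismatch_offsets %||% sample.int(w, mm)
        offs <- as.integer(offs)
        if (length(offs) != mm || any(offs < 1L | offs > w)) {
          stop("make_fixture_promoter: bad mismatch offsets in planting ", k,
               call. = FALSE)
        }
        for (o in offs) {
          word[o] <- bases[which.min(pwm$frequencies[, o])]
        }
      }
      b[idx] <- word
      owner[idx] <- paste0("planting", k)
      plant_rows[[k]] <- data.frame(
        family_code = pwm$family_code, matrix_id = pwm$matrix_id,
        start = start, end = start + w - 1L, mismatches = mm,
        mismatch_offsets = paste(offs, collapse = ","),
        mismatch_positions = paste(start + offs - 1L, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(constraints) && nrow(constraints) > 0) {
      cpos <- as.integer(constraints$position)
      cbase <- toupper(constraints$base)
      if (any(cpos < -length | cpos > -1L)) {
        stop("make_fixture_promoter: constraint out of bounds", call. = FALSE)
      }
      cidx <- upstream_to_index(cpos, length)
      clash <- claimed(cidx) & b[cidx] != cbase
      if (any(clash)) {
        stop("make_fixture_promoter: constraint/planting conflict at position(s) ",
             paste(cpos[clash], collapse = ", "), call. = FALSE)
      }
      b[cidx] <- cbase
    }
    out <- promoter_sequence(b, label = label)
    attr(out, "plantings") <- if (length(plant_rows) > 0)
      do.call(rbind, plant_rows) else NULL
    attr(out, "constraints") <- constraints
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Describe a planted expression effect for the screening simulator
#'
#' @param variant_name Variant label.
#' @param true_rf_percent True relative fluorescence in percent of the
#'   control mean (must be > 0).
#' @param condition Growth condition label (default `"inducing"`).
#' @param n_clones Number of clones (default 8).
#' @param cv Lognormal coefficient of variation of clone-to-clone specific
#'   fluorescence (default 0.1).
#' @param n_outliers Clones replaced by 5-20x outliers (default 0).
#' @param n_multicopy Clones at an integer multiple (2-4x) of the planted
#'   level, emulating multicopy integrants (default 0).
#' @param true_yield_fc Optional true secreted-protein yield fold-change;
#'   when set, `titer` and `wcw` columns are generated too.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(variant_name, true_rf_percent,
                           condition = "inducing", n_clones = 8L, cv = 0.1,
                           n_outliers = 0L, n_multicopy = 0L,
                           true_yield_fc = NULL) {
  if (true_rf_percent <= 0) stop("planted_effect: true_rf_percent must be > 0",
                                 call. = FALSE)
  if (cv < 0) stop("planted_effect: cv must be >= 0", call. = FALSE)
  structure(list(variant_name = variant_name,
                 true_rf_percent = true_rf_percent, condition = condition,
                 n_clones = as.integer(n_clones), cv = cv,
                 n_outliers = as.integer(n_outliers),
                 n_multicopy = as.integer(n_multicopy),
                 true_yield_fc = true_yield_fc), class = "planted_effect")
}

#' Generate a planted-effect screening dataset
#'
#' Emulates a deep-well-plate screening round: for each condition present
#' among the effects, `n_controls` control clones at 100% plus the
#' requested variant clones at their planted relative fluorescence.
#' Clone-level specific fluorescence is lognormal around the planted level;
#' the fluorescence channel is that value times an independently noisy
#' volume proxy, so volume normalisation is required to recover the truth.
#' Outlier clones are scaled by a random 5-20x factor, multicopy clones by
#' an integer 2-4x factor. Truth metadata (planted level, outlier and
#' multicopy flags) is returned separately and is never consumed by the
#' analysis functions.
#'
#' @param seed Integer seed.
#' @param effects List of [planted_effect()]s.
#' @param control_name Label of the control group (default `"control"`).
#' @param control_mean Mean specific fluorescence of the control (arbitrary
#'   units, default 1000).
#' @param control_cv Clone-to-clone CV of the control (default 0.1).
#' @param n_controls Control clones per condition (default 4; at least 4
#'   required, matching plate-screening practice).
#' @param volume_cv CV of the volume proxy (default 0.05).
#' @param control_yield Control product yield (mg per g WCW) used when any
#'   effect plants a yield fold-change (default 25).
#' @param wcw_mean Mean wet cell weight in g (default 2).
#' @return A list with `records` (data frame of screening records:
#'   `clone_id`, `variant_name`, `condition`, `fluorescence`,
#'   `volume_proxy`, `is_control`, and `titer`/`wcw` when yields are
#'   planted) and `truth` (per-clone planted values and flags).
#' @examples
#' ds <- make_screening_dataset(seed = 1,
#'   effects = list(planted_effect("MutB-like", 150)))
#' screen_table(ds$records, control_name = "control")
#' @export
make_screening_dataset <- function(seed, effects, control_name = "control",
                                   control_mean = 1000, control_cv = 0.1,
                                   n_controls = 4L, volume_cv = 0.05,
                                   control_yield = 25, wcw_mean = 2) {
  if (n_controls < 4L) {
    stop("make_screening_dataset: need >= 4 control clones", call. = FALSE)
  }
  stopifnot(all(vapply(effects, inherits, logical(1), "planted_effect")))
  any_yield <- any(!vapply(effects, function(e) is.null(e$true_yield_fc),
                           logical(1)))
  conds <- unique(c(vapply(effects, function(e) e$condition, character(1))))
  .with_seed(seed, {
    rec_rows <- list()
    truth_rows <- list()
    clone_counter <- 0L
    gen_group <- function(name, cond, rf, n, cv, n_out, n_multi, is_ctrl,
                          yield_fc) {
      sf <- .rlnorm_mean_cv(n, rf / 100 * control_mean, cv)
      is_out <- rep(FALSE, n)
      is_multi <- rep(FALSE, n)
      special <- if (n_out + n_multi > 0) sample.int(n, n_out + n_multi) else integer()
      if (n_out > 0) {
        oi <- special[seq_len(n_out)]
        sf[oi] <- sf[oi] * stats::runif(n_out, 5, 20)
        is_out[oi] <- TRUE
      }
      if (n_multi > 0) {
        mi <- special[n_out + seq_len(n_multi)]
        sf[mi] <- sf[mi] * sample(2:4, n_multi, replace = TRUE)
        is_multi[mi] <- TRUE
      }
      vol <- .rlnorm_mean_cv(n, 1, volume_cv)
      ids <- clone_counter + seq_len(n)
      clone_counter <<- clone_counter + n
      rec <- data.frame(clone_id = ids, variant_name = name, condition = cond,
                        fluorescence = sf * vol, volume_proxy = vol,
                        is_control = is_ctrl, stringsAsFactors = FALSE)
      if (any_yield) {
        fc <- if (is.null(yield_fc)) 1 else yield_fc
        wcw <- .rlnorm_mean_cv(n, wcw_mean, 0.05)
        yld <- .rlnorm_mean_cv(n, fc * control_yield, cv)
        rec$wcw <- wcw
        rec$titer <- yld * wcw
      }
      tru <- data.frame(clone_id = ids, variant_name = name, condition = cond,
                        true_rf = rf, is_outlier = is_out,
                        is_multicopy = is_multi,
                        true_yield_fc = if (any_yield) {
                          if (is.null(yield_fc)) 1 else yield_fc
                        } else NA_real_,
                        stringsAsFactors = FALSE)
      list(rec = rec, tru = tru)
    }
    for (cond in conds) {
      g <- gen_group(control_name, cond, 100, n_controls, control_cv, 0L, 0L,
                     TRUE, if (any_yield) 1 else NULL)
      rec_rows[[length(rec_rows) + 1L]] <- g$rec
      truth_rows[[length(truth_rows) + 1L]] <- g$tru
    }
    for (e in effects) {
      g <- gen_group(e$variant_name, e$condition, e$true_rf_percent,
                     e$n_clones, e$cv, e$n_outliers, e$n_multicopy, FALSE,
                     e$true_yield_fc)
      rec_rows[[length(rec_rows) + 1L]] <- g$rec
      truth_rows[[length(truth_rows) + 1L]] <- g$tru
    }
    list(records = do.call(rbind, c(rec_rows, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)))
  })
}
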