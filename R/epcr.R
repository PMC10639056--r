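#' Mutation spectrum of an error-prone PCR protocol
#'
#' Describes what a mutation event looks like once it happens: the split
#' between substitutions, single-nt deletions and insertions, the
#' substitution matrix (for each reference base, a distribution over the
#' three alternatives), and the relative propensity of each reference base
#' to mutate at all. The defaults reflect a Taq/MnCl2 protocol biased
#' toward mutating T (and to a lesser degree A), with 12.8% of events being
#' deletions and insertions rare; the from-base weights and the uniform
#' to-base distribution are illustrative calibration defaults and fully
#' configurable.
#'
#' @param p_substitution,p_deletion,p_insertion Event-type probabilities;
#'   must sum to 1 (within 1e-9). Defaults 0.862 / 0.128 / 0.01.
#' @param substitution_matrix 4 x 4 matrix (rows = ref A,C,G,T, cols = alt)
#'   with zero diagonal and rows summing to 1; default uniform over the
#'   three alternatives.
#' @param from_base_weights Named non-negative weights (A, C, G, T) for the
#'   relative mutability of each reference base; internally normalised to
#'   mean 1 so that the configured per-step rate remains the average
#'   per-position rate on an equal-composition template. Default
#'   `c(A = 2, C = 1, G = 1, T = 4)`.
#' @return A `mutation_spectrum` object.
#' @export
mutation_spectrum <- function(p_substitution = 0.862, p_deletion = 0.128,
                              p_insertion = 0.01, substitution_matrix = NULL,
                              from_base_weights = c(A = 2, C = 1, G = 1, T = 4)) {
  ps <- c(p_substitution, p_deletion, p_insertion)
  if (any(ps < 0) || abs(sum(ps) - 1) > 1e-9) {
    stop("mutation_spectrum: event-type probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(substitution_matrix)) {
    substitution_matrix <- matrix(1 / 3, 4, 4, dimnames = list(bases, bases))
    diag(substitution_matrix) <- 0
  }
  substitution_matrix <- as.matrix(substitution_matrix)
  if (!identical(dim(substitution_matrix), c(4L, 4L))) {
    stop("mutation_spectrum: substitution_matrix must be 4 x 4", call. = FALSE)
  }
  dimnames(substitution_matrix) <- list(bases, bases)
  if (any(diag(substitution_matrix) != 0)) {
    stop("mutation_spectrum: substitution_matrix diagonal must be 0", call. = FALSE)
  }
  if (any(abs(rowSums(substitution_matrix) - 1) > 1e-9)) {
    stop("mutation_spectrum: substitution_matrix rows must sum to 1", call. = FALSE)
  }
  w <- from_base_weights[bases]
  if (anyNA(w) || any(w < 0) || all(w == 0)) {
    stop("mutation_spectrum: from_base_weights must be named non-negative (A,C,G,T)",
         call. = FALSE)
  }
  structure(list(
    p_substitution = p_substitution,
    p_deletion = p_deletion,
    p_insertion = p_insertion,
    substitution_matrix = substitution_matrix,
    from_base_weights = w / mean(w)
  ), class = "mutation_spectrum")
}

#' Error-prone PCR library configuration
#'
#' The library model: each clone derives from one mutagenesis step, drawn
#' from `pooling_weights` (equimolar pooling by default), and carries
#' independent per-position mutations at that step's cumulative rate. The
#' default step rates 1.5% / 2.7% / 3.4% per nt are the endpoint average
#' mutation rates of a three-step serial EP-PCR; the default region
#' -457..-137 is the 321-nt TFBS-dense main regulatory segment such
#' protocols target.
#'
#' @param region Length-2 integer vector `c(start, end)` of upstream
#'   positions bounding the mutagenised region.
#' @param step_rates Per-step average mutation rates per nt.
#' @param pooling_weights Per-step pooling weights; normalised to sum to 1.
#'   Default equimolar.
#' @param n_clones Number of clones to simulate.
#' @param seed Integer seed making the whole library reproducible.
#' @return An `epcr_config` object.
#' @export
epcr_config <- function(region = c(-457L, -137L),
                        step_rates = c(0.015, 0.027, 0.034),
                        pooling_weights = NULL, n_clones = 100L,
                        seed = 1L) {
  if (length(region) != 2L || region[1] > region[2]) {
    stop("epcr_config: region must be c(start, end) with start <= end",
         call. = FALSE)
  }
  if (any(step_rates < 0 | step_rates > 1)) {
    stop("epcr_config: step rates must be in [0, 1]", call. = FALSE)
  }
  if (is.null(pooling_weights)) {
    pooling_weights <- rep(1 / length(step_rates), length(step_rates))
  }
  if (length(pooling_weights) != length(step_rates) || any(pooling_weights < 0) ||
      sum(pooling_weights) <= 0) {
    stop("epcr_config: pooling_weights must be non-negative, one per step",
         call. = FALSE)
  }
  structure(list(
    region = as.integer(region),
    step_rates = step_rates,
    pooling_weights = pooling_weights / sum(pooling_weights),
    n_clones = as.integer(n_clones),
    seed = as.integer(seed)
  ), class = "epcr_config")
}

# One clone's mutations at a given per-position rate. Uses the current RNG
# stream. `positions` are the upstream positions reported for the region.
.simulate_clone_impl <- function(bases, positions, rate, spectrum) {
  n <- length(bases)
  w <- spectrum$from_base_weights[bases]
  p <- pmin(1, rate * w)
  hit <- stats::runif(n) < p
  k <- sum(hit)
  if (k == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(hit)
  types <- sample(c("substitution", "deletion", "insertion"), k, replace = TRUE,
                  prob = c(spectrum$p_substitution, spectrum$p_deletion,
                           spectrum$p_insertion))
  ref <- bases[idx]
  alt <- character(k)
  all_bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    alt[j] <- switch(types[j],
      substitution = sample(all_bases, 1L,
                            prob = spectrum$substitution_matrix[ref[j], ]),
      deletion = NA_character_,
      insertion = sample(all_bases, 1L)
    )
  }
  data.frame(position = positions[idx], ref = ref, alt = alt, kind = types,
             stringsAsFactors = FALSE)
}

#' Simulate one EP-PCR clone
#'
#' Each position of the region mutates independently with probability
#' `rate` times the (mean-1 normalised) from-base weight of its reference
#' base; mutated positions then draw an event type and, for substitutions,
#' an alternative base from the spectrum. Uses the current RNG stream —
#' seed upstream (or via [simulate_library()]) for reproducibility.
#'
#' @param region_seq A [promoter_sequence()] for the mutagenised region.
#' @param rate Average per-position mutation rate in \[0, 1\].
#' @param spectrum A [mutation_spectrum()].
#' @return Data frame with columns `position` (the region's own upstream
#'   coordinates unless it carries a `region` attribute from
#'   [extract_region()], in which case original coordinates are used),
#'   `ref`, `alt` (`NA` for deletions) and `kind`.
#' @export
simulate_clone <- function(region_seq, rate, spectrum = mutation_spectrum()) {
  stopifnot(is_promoter_sequence(region_seq))
  if (rate < 0 || rate > 1) stop("simulate_clone: rate must be in [0, 1]",
                                 call. = FALSE)
  L <- length(region_seq)
  reg <- attr(region_seq, "region")
  positions <- if (!is.null(reg)) seq(reg[1], reg[2]) else seq(-L, -1L)
  .simulate_clone_impl(region_seq$bases, positions, rate, spectrum)
}

#' Simulate an error-prone PCR mutant library
#'
#' Draws each clone's mutagenesis step from the pooling weights, then
#' simulates its mutations with [simulate_clone()] at that step's rate.
#' Fully reproducible from `config$seed`; the caller's RNG state is
#' restored afterwards.
#'
#' @param config An [epcr_config()].
#' @param spectrum A [mutation_spectrum()].
#' @param promoter A [promoter_sequence()]; the configured region is
#'   extracted from it and mutations are reported in its coordinates. A
#'   sequence exactly covering the region is also accepted.
#' @return An `epcr_library`: list with `mutations` (data frame: `clone_id`,
#'   `step`, `position`, `ref`, `alt`, `kind`), `clone_steps`, `n_clones`,
#'   `config`, `spectrum`.
#' @examples
#' prom <- make_fixture_promoter(seed = 1, constraints = NULL)
#' lib <- simulate_library(epcr_config(n_clones = 20, seed = 7),
#'                         mutation_spectrum(), prom)
#' library_stats(lib)$mean_mutations_per_clone
#' @export
simulate_library <- function(config, spectrum = mutation_spectrum(), promoter) {
  stopifnot(inherits(config, "epcr_config"),
            inherits(spectrum, "mutation_spectrum"),
            is_promoter_sequence(promoter))
  reg_len <- config$region[2] - config$region[1] + 1L
  if (length(promoter) == reg_len && is.null(attr(promoter, "region"))) {
    region_seq <- promoter
    attr(region_seq, "region") <- config$region
  } else {
    region_seq <- extract_region(promoter, config$region[1], config$region[2])
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  steps <- sample.int(length(config$step_rates), config$n_clones,
                      replace = TRUE, prob = config$pooling_weights)
  rows <- vector("list", config$n_clones)
  for (i in seq_len(config$n_clones)) {
    m <- .simulate_clone_impl(region_seq$bases,
                              seq(config$region[1], config$region[2]),
                              config$step_rates[steps[i]], spectrum)
    if (nrow(m) > 0L) {
      m$clone_id <- i
      m$step <- steps[i]
      rows[[i]] <- m[, c("clone_id", "step", "position", "ref", "alt", "kind")]
    }
  }
  muts <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                           make.row.names = FALSE))
  if (is.null(muts)) {
    muts <- data.frame(clone_id = integer(), step = integer(),
                       position = integer(), ref = character(),
                       alt = character(), kind = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(mutations = muts, clone_steps = steps,
                 n_clones = config$n_clones, config = config,
                 spectrum = spectrum), class = "epcr_library")
}

#' @export
print.epcr_library <- function(x, ...) {
  cat(sprintf("<epcr_library> %d clones, %d mutation events\n",
              x$n_clones, nrow(x$mutations)))
  invisible(x)
}

.is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Summary statistics of a simulated EP-PCR library
#'
#' @param library An `epcr_library` from [simulate_library()].
#' @return A `library_stats` list: `n_clones`, `n_events`,
#'   `median_mutations_per_clone`, `mean_mutations_per_clone`,
#'   `substitution_fraction`, `deletion_fraction`, `insertion_fraction`
#'   (fractions of all events; they sum to 1), `transition_fraction`
#'   (among substitutions), `n_unique_variants` (distinct mutation sets,
#'   the unmutated clone counting as one), and `per_position_hit_counts`
#'   (named integer vector over mutated positions). Statistics are
#'   invariant to clone order.
#' @export
library_stats <- function(library) {
  stopifnot(inherits(library, "epcr_library"))
  m <- library$mutations
  if (library$n_clones < 1L) stop("library_stats: empty library", call. = FALSE)
  counts <- integer(library$n_clones)
  if (nrow(m) > 0L) {
    tab <- table(factor(m$clone_id, levels = seq_len(library$n_clones)))
    counts <- as.integer(tab)
  }
  n_events <- nrow(m)
  subs <- m[m$kind == "substitution", , drop = FALSE]
  sig <- vapply(seq_len(library$n_clones), function(i) {
    rows <- m[m$clone_id == i, , drop = FALSE]
    rows <- rows[order(rows$position, rows$kind, rows$alt), , drop = FALSE]
    paste(rows$position, rows$kind, rows$ref, rows$alt, sep = ":", collapse = "|")
  }, character(1))
  structure(list(
    n_clones = library$n_clones,
    n_events = n_events,
    median_mutations_per_clone = stats::median(counts),
    mean_mutations_per_clone = mean(counts),
    substitution_fraction = if (n_events > 0) sum(m$kind == "substitution") / n_events else NA_real_,
    deletion_fraction = if (n_events > 0) sum(m$kind == "deletion") / n_events else NA_real_,
    insertion_fraction = if (n_events > 0) sum(m$kind == "insertion") / n_events else NA_real_,
    transition_fraction = if (nrow(subs) > 0)
      mean(.is_transition(subs$ref, subs$alt)) else NA_real_,
    n_unique_variants = length(unique(sig)),
    per_position_hit_counts = if (n_events > 0) table(m$position) else table(integer())
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<library_stats> %d clones, %d events\n",
    "  mutations/clone: median %.1f, mean %.2f\n",
    "  events: %.1f%% substitutions, %.1f%% deletions, %.1f%% insertions\n",
    "  transitions among substitutions: %.1f%%\n",
    "  unique variants: %d\n"),
    x$n_clones, x$n_events, x$median_mutations_per_clone,
    x$mean_mutations_per_clone, 100 * x$substitution_fraction,
    100 * x$deletion_fraction, 100 * x$insertion_fraction,
    100 * x$transition_fraction, x$n_unique_variants))
  invisible(x)
}

#' Write per-clone mutation lists as TSV
#'
#' One row per clone: `clone_id`, `step`, `n_mutations`, and the
#' comma-joined mutation notations.
#'
#' @param library An `epcr_library`.
#' @param path Output path.
#' @export
write_library_tsv <- function(library, path) {
  stopifnot(inherits(library, "epcr_library"))
  m <- library$mutations
  nota <- vapply(seq_len(library$n_clones), function(i) {
    rows <- m[m$clone_id == i, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    paste(vapply(seq_len(nrow(rows)), function(j) {
      format_mutation(point_mutation(rows$position[j],
                                     ref = rows$ref[j],
                                     alt = rows$alt[j],
                                     kind = rows$kind[j]))
    }, character(1)), collapse = ",")
  }, character(1))
  out <- data.frame(clone_id = seq_len(library$n_clones),
                    step = library$clone_steps,
                    n_mutations = as.integer(table(factor(m$clone_id,
                      levels = seq_len(library$n_clones)))),
                    mutations = nota, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
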