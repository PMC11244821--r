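#' Group nearby mutations into superloci
#'
#' Complex mutation events often appear as several called mutations
#' within a short stretch of sequence. Within each strain and
#' chromosome, mutations whose successive positions differ by at most
#' `window` base pairs are chained into a single "superlocus". Chaining
#' is transitive by default (A-B <= window and B-C <= window groups all
#' three even if A-C exceeds the window), which makes the result
#' independent of input order; `mode = "strict"` instead starts a new
#' locus whenever a mutation is more than `window` bp from the *first*
#' member of the current chain.
#'
#' @param mutations data frame with columns `strain_id`, `chromosome`,
#'   `position` (1-based), and optionally `mutation_class`, `impact`,
#'   `gene`.
#' @param window grouping window in bp (default 50).
#' @param mode `"transitive"` (default) or `"strict"` (see Details).
#' @return The input with an added integer `superlocus` column (global
#'   locus index) plus attribute `n_loci`.
#' @examples
#' mut <- data.frame(strain_id = "a", chromosome = "I",
#'                   position = c(100, 130, 200))
#' attr(group_superloci(mut), "n_loci") # 2
#' @export
group_superloci <- function(mutations, window = 50,
                            mode = c("transitive", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(c("strain_id", "chromosome", "position") %in%
                  names(mutations)))
  if (any(mutations$position < 1)) {
    stop_domain("positions must be >= 1")
  }
  ord <- order(mutations$strain_id, mutations$chromosome,
               mutations$position)
  m <- mutations[ord, , drop = FALSE]
  n <- nrow(m)
  locus <- integer(n)
  if (n > 0) {
    locus[1] <- 1L
    anchor <- m$position[1]
    for (i in seq_len(n)[-1]) {
      same_group <- m$strain_id[i] == m$strain_id[i - 1] &&
        m$chromosome[i] == m$chromosome[i - 1]
      ref_pos <- if (mode == "transitive") m$position[i - 1] else anchor
      if (same_group && m$position[i] - ref_pos <= window) {
        locus[i] <- locus[i - 1]
      } else {
        locus[i] <- locus[i - 1] + 1L
        anchor <- m$position[i]
      }
    }
  }
  res <- mutations
  res$superlocus <- NA_integer_
  res$superlocus[ord] <- locus
  attr(res, "n_loci") <- if (n) max(locus) else 0L
  res
}

IMPACT_LEVELS <- c("none", "modifier", "low", "moderate", "high")

#' Most severe mutational impact per strain or gene
#'
#' Aggregates predicted impact labels (snpEff vocabulary: `high` >
#' `moderate` > `low` > `modifier` > `none`) to the most severe label in
#' each group. Groups without mutations map to `"none"`.
#'
#' @param records data frame with columns `impact` and the grouping
#'   column (`strain_id` or `gene`).
#' @param group_by `"strain_id"` or `"gene"`.
#' @param groups optional vector of group identifiers to report
#'   (e.g. all strains, including mutation-free ones).
#' @return Named character vector mapping group to its most severe
#'   impact.
#' @export
most_severe_impact <- function(records, group_by = c("strain_id", "gene"),
                               groups = NULL) {
  group_by <- match.arg(group_by)
  bad <- setdiff(unique(records$impact), IMPACT_LEVELS)
  if (length(bad)) {
    stop_domain("unknown impact label(s): ", paste(bad, collapse = ", "))
  }
  lev <- factor(records$impact, levels = IMPACT_LEVELS, ordered = TRUE)
  agg <- tapply(lev, records[[group_by]],
                function(x) as.character(max(x)))
  out <- stats::setNames(as.character(agg), names(agg))
  if (!is.null(groups)) {
    full <- stats::setNames(rep("none", length(groups)),
                            as.character(groups))
    full[names(out)] <- out
    out <- full
  }
  out
}

#' Mean per-mutation effect from a per-generation effect rate
#'
#' Converts an observed mean change in selection coefficient per 100
#' generations of mutation accumulation into a mean effect per mutation,
#' given the mean number of mutations accumulated per strain over a
#' reference duration. For instance, a mean decrease of 0.0024 in `s`
#' per 100 generations with 1.8 SSR mutations per 200-generation strain
#' gives about 0.0027 (0.3%) per mutation.
#'
#' @param s_change_per_100gen mean change in `s` per 100 generations
#'   (magnitude).
#' @param mutations_per_strain mean mutations accumulated per strain
#'   over `generations` generations.
#' @param generations duration over which `mutations_per_strain` was
#'   counted (default 200).
#' @return Mean effect magnitude per mutation.
#' @export
per_mutation_effect <- function(s_change_per_100gen, mutations_per_strain,
                                generations = 200) {
  if (mutations_per_strain <= 0 || generations <= 0) {
    stop_domain("mutation count and generations must be > 0")
  }
  s_change_per_100gen * (generations / 100) / mutations_per_strain
}
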