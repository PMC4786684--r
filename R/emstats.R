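#' Normalize per-process event counts by process area
#'
#' Divides each event count by the area of its microglial process (um^2),
#' giving per-process event densities, then averages processes within each
#' animal. Rows with non-positive area are rejected with a warning.
#'
#' @param table data frame with columns `animal`, `group`, `process`,
#'   `area_um2`, and one or more integer event-count columns (e.g.
#'   `cleft_contacts`, `inclusions`, `element_contacts`).
#' @param categories names of the count columns; default: every numeric
#'   column other than `area_um2`.
#' @return list with `per_process` (densities, events/um^2) and `per_animal`
#'   (animal means per category, the unit of replication for group stats).
#' @export
normalize_events <- function(table, categories = NULL) {
  need <- c("animal", "group", "area_um2")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("area_um2", "process"))
  }
  if (length(categories) == 0L) stop("no event-count columns found", call. = FALSE)
  bad <- !is.finite(table$area_um2) | table$area_um2 <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive area rejected")
    table <- table[!bad, , drop = FALSE]
  }
  cnts <- as.matrix(table[categories])
  if (any(cnts < 0)) stop("event counts must be non-negative", call. = FALSE)
  dens <- sweep(cnts, 1L, table$area_um2, `/`)
  per_process <- cbind(table[intersect(c("animal", "group", "process", "area_um2"),
                                       names(table))],
                       as.data.frame(dens))
  per_animal <- stats::aggregate(per_process[categories],
                                 by = list(animal = per_process$animal,
                                           group = per_process$group),
                                 FUN = mean)
  list(per_process = per_process, per_animal = per_animal,
       categories = categories)
}

# Two-sided Grubbs critical value at significance `alpha` for sample size n:
# ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2)) with t the upper alpha/(2n)
# t-quantile at n-2 degrees of freedom (alpha/n when one-sided).
grubbs_critical <- function(n, alpha, two_sided = TRUE) {
  p <- if (two_sided) alpha / (2 * n) else alpha / n
  t <- stats::qt(1 - p, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' One-pass Grubbs outlier removal
#'
#' Computes the Grubbs statistic G = max|x - mean(x)| / sd(x) and removes
#' the single most extreme value if and only if G exceeds the critical value
#' at significance `alpha`. Applied exactly once - never iterated - which
#' matches its intended use here: discarding the occasional exceptionally
#' small process whose area normalization produces a huge density. Ties are
#' broken toward the first-occurring extreme. A zero-variance sample removes
#' nothing.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @param two_sided test both tails (default) or only the upper tail.
#' @return list with `retained`, `removed` (the value, or `NULL`),
#'   `removed_index`, `G`, `critical`.
#' @export
grubbs_remove_once <- function(values, alpha = 0.05, two_sided = TRUE) {
  if (length(values) < 3L) stop("Grubbs test needs n >= 3", call. = FALSE)
  check_positive(alpha, "alpha")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(retained = values, removed = NULL, removed_index = NA_integer_,
                G = 0, critical = grubbs_critical(length(values), alpha, two_sided)))
  }
  dev <- if (two_sided) abs(values - mean(values)) else values - mean(values)
  i <- which.max(dev)
  G <- dev[i] / s
  crit <- grubbs_critical(length(values), alpha, two_sided)
  if (G > crit) {
    list(retained = values[-i], removed = values[i], removed_index = i,
         G = G, critical = crit)
  } else {
    list(retained = values, removed = NULL, removed_index = NA_integer_,
         G = G, critical = crit)
  }
}

#' Group summary of area-normalized event densities
#'
#' Aggregates per-process densities to per-animal means, then reports group
#' mean +/- s.e.m. per event category with the animal as the unit of n. An
#' optional one-pass Grubbs step (per category, across all per-process
#' densities) removes a single extreme density before aggregation.
#'
#' @param table raw [normalize_events()] input table.
#' @param grubbs apply [grubbs_remove_once()] per category first.
#' @param alpha Grubbs significance level.
#' @param two_sided Grubbs sidedness.
#' @return list with `summary` (data frame: group, category, mean_density,
#'   sem, n_animals), `per_animal`, `grubbs` (per-category removal records).
#' @export
summarize_groups <- function(table, grubbs = FALSE, alpha = 0.05,
                             two_sided = TRUE) {
  norm <- normalize_events(table)
  pp <- norm$per_process
  removals <- list()
  if (grubbs) {
    for (cat in norm$categories) {
      res <- grubbs_remove_once(pp[[cat]], alpha = alpha, two_sided = two_sided)
      removals[[cat]] <- res
      if (!is.null(res$removed)) pp[[cat]][res$removed_index] <- NA_real_
    }
  }
  per_animal <- stats::aggregate(pp[norm$categories],
                                 by = list(animal = pp$animal, group = pp$group),
                                 FUN = mean, na.rm = TRUE)
  rows <- list()
  for (g in unique(per_animal$group)) {
    sub <- per_animal[per_animal$group == g, , drop = FALSE]
    for (cat in norm$categories) {
      x <- sub[[cat]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, category = cat, mean_density = mean(x),
        sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
        n_animals = length(x)
      )
    }
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       per_animal = per_animal, grubbs = if (grubbs) removals else NULL)
}
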