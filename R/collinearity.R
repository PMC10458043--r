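#' Pairwise Pearson correlation between stack layers
#'
#' Computes the correlation matrix over cells that are valid in *both*
#' layers of each pair, the first half of a collinearity-pruning step.
#' Categorical layers are excluded from the matrix and are always retained
#' downstream.  A zero-variance layer has undefined correlations; these are
#' reported and treated as uncorrelated (r = 0) with a warning.
#'
#' @param stack A [raster_stack()] with at least two continuous layers.
#' @param mask Optional logical matrix restricting the cells used.
#' @return A `correlation_report`: list with `variables`, `matrix`
#'   (symmetric, unit diagonal), `categorical` (names passed through),
#'   `zero_variance` (names), and empty `cutoff`/`groups`/`retained` slots
#'   filled in by [remove_collinear()].
#' @export
correlation_matrix <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "raster_stack"))
  kinds <- vapply(stack$layers, function(l) l$kind, "")
  cont <- names(stack$layers)[kinds == "continuous"]
  cats <- names(stack$layers)[kinds == "categorical"]
  if (length(cont) < 2)
    stop("need at least 2 continuous layers", call. = FALSE)
  vals <- lapply(stack$layers[cont], function(l) {
    v <- l$values
    if (!is.null(mask)) v[!mask] <- NA
    as.vector(v)
  })
  p <- length(cont)
  zv <- character(0)
  for (nm in cont) {
    v <- vals[[nm]]
    if (stats::var(v[!is.na(v)]) == 0) zv <- c(zv, nm)
  }
  if (length(zv))
    warning("zero-variance layer(s) treated as uncorrelated: ",
            paste(zv, collapse = ", "), call. = FALSE)
  m <- diag(1, p)
  dimnames(m) <- list(cont, cont)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- vals[[i]]; b <- vals[[j]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3)
        stop("fewer than 3 jointly valid cells for ", cont[i], " vs ",
             cont[j], call. = FALSE)
      r <- if (cont[i] %in% zv || cont[j] %in% zv) 0
           else stats::cor(a[ok], b[ok])
      m[i, j] <- m[j, i] <- r
    }
  }
  structure(list(variables = cont, matrix = m, categorical = cats,
                 zero_variance = zv, cutoff = NA_real_, groups = NULL,
                 retained = NULL),
            class = "correlation_report")
}

#' Prune collinear variables at a cutoff
#'
#' Variables are linked whenever `|r| >= cutoff`; collinear groups are the
#' connected components of that graph (single linkage, so two retained
#' variables from different groups always have `|r| < cutoff`, while within
#' a group linkage may be transitive).  One representative is kept per
#' group — the lexicographically first name by default, or a seeded random
#' member to emulate tools that pick at random.  Categorical variables are
#' appended to the retained list unchanged.
#'
#' @param report A `correlation_report` from [correlation_matrix()].
#' @param cutoff Absolute-correlation threshold in `(0, 1]` (default 0.8).
#' @param representative `"lexicographic"` (default) or `"random"`.
#' @param seed Seed used when `representative = "random"`.
#' @return The report with `cutoff`, `groups` (list of character vectors)
#'   and `retained` (character vector) filled in.
#' @export
remove_collinear <- function(report, cutoff = 0.8,
                             representative = c("lexicographic", "random"),
                             seed = 1L) {
  representative <- match.arg(representative)
  stopifnot(inherits(report, "correlation_report"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  vars <- report$variables
  p <- length(vars)
  # tiny slack so duplicated layers (r = 1 up to rounding) still link at
  # cutoff = 1
  adj <- abs(report$matrix) >= cutoff - 1e-12
  diag(adj) <- FALSE
  # connected components by repeated expansion
  comp <- rep(NA_integer_, p)
  k <- 0L
  for (i in seq_len(p)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- k
      frontier <- nb
    }
  }
  groups <- lapply(seq_len(k), function(g) sort(vars[comp == g]))
  pick <- if (representative == "lexicographic") {
    vapply(groups, `[`, "", 1L)
  } else {
    withr::with_seed(seed,
      vapply(groups, function(g) g[sample.int(length(g), 1L)], ""))
  }
  report$cutoff <- cutoff
  report$groups <- groups
  report$retained <- c(sort(pick), report$categorical)
  report
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d continuous variable(s)",
              length(x$variables)))
  if (!is.na(x$cutoff))
    cat(sprintf(", cutoff %.2f -> %d retained (+%d categorical)",
                x$cutoff, length(x$groups), length(x$categorical)))
  cat("\n")
  invisible(x)
}

#' Write a correlation report to disk
#'
#' @param report A `correlation_report`.
#' @param matrix_path CSV path for the correlation matrix.
#' @param retained_path Optional plain-text path for the retained list.
#' @return `matrix_path`, invisibly.
#' @export
write_correlation_report <- function(report, matrix_path,
                                     retained_path = NULL) {
  utils::write.csv(report$matrix, matrix_path)
  if (!is.null(retained_path) && !is.null(report$retained))
    writeLines(report$retained, retained_path)
  invisible(matrix_path)
}
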