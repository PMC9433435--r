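#' Per-branch nonsynonymous proportions
#'
#' Computes P = dN/(dN+dS) per gene and branch, then averages the per-gene
#' proportions per branch (genes contributing no changes on a branch are
#' excluded from that branch's average and counted in `n_genes_dropped`).
#' Branches are labelled `ancestral` or `alternative` according to the
#' reconstructed state of their child node.
#'
#' The age covariate is the parent-node age: for terminal branches on an
#' ultrametric tree this equals the branch length, matching the
#' "branch length/node age" usage for dated trees.
#'
#' @param changes A `branch_change_table`.
#' @param tree A `dated_tree`.
#' @param rec A `parsimony_asr` (or any object with `node_states$state`).
#' @param ancestral_state State treated as ancestral; defaults to the
#'   reconstruction's root state.
#' @return Tibble of class `branch_proportions`: `node`, `label`,
#'   `is_terminal`, `P`, `age`, `group`, `state`, `n_genes`,
#'   `n_genes_dropped`. Branches with no usable gene are dropped with a
#'   warning.
#' @export
branch_proportions <- function(changes, tree, rec,
                               ancestral_state = rec$root_state) {
  st <- rec$node_states$state
  out <- changes |>
    filter(!is.na(.data$P)) |>
    group_by(.data$node, .data$label, .data$is_terminal, .data$parent_age) |>
    summarise(P = mean(.data$P), n_genes = n(), .groups = "drop")
  dropped <- changes |>
    group_by(.data$node) |>
    summarise(n_genes_dropped = sum(is.na(.data$P)), .groups = "drop")
  lost <- setdiff(unique(changes$node), out$node)
  if (length(lost)) {
    warning(length(lost), " branch(es) with no changes in any gene dropped: ",
            paste(head(lost, 5), collapse = ", "))
  }
  out <- out |>
    left_join(dropped, by = "node") |>
    mutate(age = .data$parent_age,
           state = st[.data$node],
           group = ifelse(.data$state == ancestral_state, "ancestral", "alternative")) |>
    select("node", "label", "is_terminal", "P", "age", "group", "state",
           "n_genes", "n_genes_dropped")
  class(out) <- c("branch_proportions", class(out))
  attr(out, "ancestral_state") <- ancestral_state
  out
}

# branches (child node ids) on the paths from each member tip back to, but
# not including, the divergence node
path_branches <- function(tree, tips, divergence_node) {
  td <- tidy_tree(tree)
  out <- integer(0)
  for (tip in tips) {
    v <- tip
    while (!is.na(v) && v != divergence_node) {
      out <- c(out, v)
      v <- td$parent[v]
    }
  }
  sort(unique(out))
}

#' Shift-versus-sister clade comparison
#'
#' For every life-form shift event, the shift side is the set of terminal
#' and internal branches on the paths from the member taxa back to (not
#' including) the divergence node; the sister side is built symmetrically
#' from the divergence node's other child lineages, restricted to branches
#' reconstructed in the ancestral state (nested second shifts are
#' excluded). Each side's proportions are averaged with equal weight per
#' branch, the per-event share is
#' 100 * shift_mean / (shift_mean + sister_mean), and a paired t test
#' compares the two sides across events.
#'
#' @param events Tibble from [count_state_shifts()].
#' @param proportions A `branch_proportions` tibble.
#' @param tree A `dated_tree`.
#' @param rec The `parsimony_asr` used for `proportions`.
#' @return Object of class `shift_comparison`: `comparisons` (tibble per
#'   event: `event`, `derived_state`, `shift_mean_P`, `sister_mean_P`,
#'   `shift_share_pct`, `sister_share_pct`, branch list-columns) and
#'   `test` (paired t across events).
#' @export
shift_vs_sister <- function(events, proportions, tree, rec) {
  if (!nrow(events)) stop("no shift events to compare")
  st <- rec$node_states$state
  ancestral <- attr(proportions, "ancestral_state")
  Pmap <- setNames(proportions$P, proportions$node)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    div <- ev$divergence_node
    if (is.na(div)) stop("event ", ev$event, " originates at the root; no sister side")
    member_tips <- match(ev$members[[1]], tree$phylo$tip.label)
    shift_br <- path_branches(tree, member_tips, div)
    sister_roots <- ev$sister_nodes[[1]]
    sister_tipsets <- lapply(sister_roots, function(n) node_tips(tree, n))
    sister_tips <- unlist(sister_tipsets)
    sister_tips <- sister_tips[st[sister_tips] == ancestral]
    sister_br <- path_branches(tree, sister_tips, div)
    sister_br <- sister_br[st[sister_br] == ancestral]
    shift_P <- Pmap[as.character(shift_br)]
    sister_P <- Pmap[as.character(sister_br)]
    shift_P <- shift_P[!is.na(shift_P)]
    sister_P <- sister_P[!is.na(sister_P)]
    if (!length(sister_P)) {
      stop("event ", ev$event, " (", ev$derived_state,
           "): sister side has no counted branches")
    }
    if (!length(shift_P)) {
      stop("event ", ev$event, " (", ev$derived_state,
           "): shift side has no counted branches")
    }
    sm <- mean(shift_P); ss <- mean(sister_P)
    tot <- sm + ss
    share <- if (tot > 0) 100 * sm / tot else 50  # both sides zero: a tie
    tibble(event = ev$event, derived_state = ev$derived_state,
           shift_mean_P = sm, sister_mean_P = ss,
           shift_share_pct = share,
           sister_share_pct = 100 - share,
           n_shift_branches = length(shift_P),
           n_sister_branches = length(sister_P),
           shift_branches = list(shift_br), sister_branches = list(sister_br))
  })
  comp <- bind_rows(rows)
  test <- if (nrow(comp) >= 2) {
    paired_t_test(comp$shift_mean_P, comp$sister_mean_P)
  } else {
    tibble(t = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  structure(list(comparisons = comp, test = test), class = "shift_comparison")
}

#' @export
print.shift_comparison <- function(x, ...) {
  cat("<shift_comparison>", nrow(x$comparisons), "events; paired t =",
      format(x$test$t, digits = 4), "df =", x$test$df,
      "p =", format(x$test$p_value, digits = 4), "\n")
  print(select(x$comparisons, "event", "derived_state", "shift_mean_P",
               "sister_mean_P", "shift_share_pct"))
  invisible(x)
}

#' Classical paired t test
#'
#' Two-sided paired t on the element-wise differences, df = n - 1. A
#' zero-variance difference vector yields t = 0, p = 1 when all
#' differences are zero, and a signed infinite-t sentinel with p = 0
#' otherwise.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Tibble: `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(t = 0, df = n - 1L, p_value = 1, mean_difference = 0))
    }
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1L, p_value = 0,
                  mean_difference = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
         p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Nonsynonymous proportion against branch age, by group
#'
#' Ordinary least squares of P on age within each reconstruction group,
#' plus a joint F test of group equality: the full model
#' `P ~ age * group` is compared with the reduced `P ~ age` (two degrees
#' of freedom: group main effect and group x age interaction).
#'
#' @param proportions A `branch_proportions` tibble (or any tibble with
#'   `P`, `age`, `group`).
#' @param level Confidence level for the bands.
#' @return Object of class `age_regression`: `per_group` (slope,
#'   intercept, r.squared per group), `equality` (F, df, p), `bands`
#'   (fitted values with confidence limits on an age grid), `models`.
#' @export
regression_vs_age <- function(proportions, level = 0.95) {
  dat <- as_tibble(proportions)[, c("P", "age", "group")]
  dat <- dat[stats::complete.cases(dat), ]
  cnt <- table(dat$group)
  if (any(cnt < 3)) {
    stop("each group needs at least 3 points; got ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "))
  }
  per_group <- dat |>
    group_by(.data$group) |>
    summarise({
      m <- lm(P ~ age, data = dplyr::pick(dplyr::everything()))
      tibble(intercept = stats::coef(m)[1], slope = stats::coef(m)[2],
             r_squared = summary(m)$r.squared, n = length(m$residuals))
    }, .groups = "drop")
  reduced <- lm(P ~ age, data = dat)
  full <- lm(P ~ age * group, data = dat)
  a <- anova(reduced, full)
  Fv <- a$F[2]; pv <- a$`Pr(>F)`[2]
  if (is.na(Fv)) {  # identical fits: zero extra sum of squares
    Fv <- 0; pv <- 1
  }
  equality <- tibble(F = Fv, df1 = a$Df[2], df2 = a$Res.Df[2], p_value = pv)
  bands <- dat |>
    group_by(.data$group) |>
    dplyr::reframe({
      m <- lm(P ~ age, data = dplyr::pick(dplyr::everything()))
      grid <- seq(min(.data$age), max(.data$age), length.out = 50)
      pr <- predict(m, newdata = data.frame(age = grid),
                    interval = "confidence", level = level)
      tibble(age = grid, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
    })
  structure(list(per_group = per_group, equality = equality, bands = bands,
                 models = list(reduced = reduced, full = full), data = dat,
                 level = level),
            class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat("<age_regression>\n")
  print(x$per_group)
  cat("group equality: F =", format(x$equality$F, digits = 4),
      "p =", format(x$equality$p_value, digits = 4), "\n")
  invisible(x)
}

#' Classify selection direction from omega
#'
#' Purifying when omega < 1 - tol, diversifying when omega > 1 + tol,
#' neutral otherwise; `NA` omega gives "undetermined". The default
#' tolerance treats |omega - 1| <= 0.05 as satisfying neutrality.
#'
#' @param omega Numeric vector.
#' @param tol Neutrality half-width.
#' @return Character vector.
#' @examples
#' classify_selection(c(0.2, 1.0, 3.2, NA))
#' @export
classify_selection <- function(omega, tol = 0.05) {
  out <- dplyr::case_when(
    is.na(omega) ~ "undetermined",
    omega < 1 - tol ~ "purifying",
    omega > 1 + tol ~ "diversifying",
    TRUE ~ "neutral")
  out
}
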