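#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r and the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n-2 degrees of freedom.
#'
#' @param x,y numeric vectors, equal length >= 3, both non-constant.
#' @return list `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    jf_stop("jf_parameter_error", "need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    jf_stop("jf_degenerate_error", "correlation undefined for constant input")
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after linear regression on
#' the `controls` columns (residual method); with zero controls this reduces
#' exactly to [pearson_with_p()]. p-value from the t transform with
#' n - k - 2 degrees of freedom (k = number of controls).
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix (columns = control variables) or NULL.
#' @return list `r`, `p`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0 || length(controls) == 0)
    return(c(pearson_with_p(x, y), list(k = 0L)))
  C <- as.matrix(controls)
  n <- length(x); k <- ncol(C)
  if (nrow(C) != n)
    jf_stop("jf_parameter_error", "controls must have one row per observation")
  if (n <= k + 2)
    jf_stop("jf_parameter_error", "need n > #controls + 2")
  if (qr(cbind(1, C))$rank < k + 1)
    jf_stop("jf_rank_error", "collinear control variables")
  rx <- stats::lm.fit(cbind(1, C), x)$residuals
  ry <- stats::lm.fit(cbind(1, C), y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    jf_stop("jf_degenerate_error", "residuals constant after controlling")
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, k = k))
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df), n = n, k = k)
}

#' Significance markers for correlation displays
#'
#' Two schemes, matching the study's figure captions: `"standard"` for the
#' ion-flavor Pearson panel (`**` p <= 0.01, `*` p <= 0.05) and `"partial"`
#' for the jar-parameter partial correlations (`++` p <= 0.05, `+` p <= 0.1).
#' Boundaries are inclusive.
#'
#' @param p p-value in `[0, 1]`.
#' @param scheme `"standard"` or `"partial"`.
#' @return marker string.
#' @export
star_marks <- function(p, scheme = c("standard", "partial")) {
  scheme <- match.arg(scheme)
  if (!is.finite(p) || p < 0 || p > 1)
    jf_stop("jf_parameter_error", "p must lie in [0, 1]")
  if (scheme == "standard") {
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  } else {
    if (p <= 0.05) "++" else if (p <= 0.1) "+" else ""
  }
}

#' Percent change of a substance between two jars
#'
#' `100 * (c_b - c_a) / c_a` at the given month, relative to `jar_a`.
#' Replicate-collapsed tables use the single stored value; otherwise
#' replicates are averaged within jar. A zero baseline flags the contrast as
#' undefined rather than fabricating a number.
#'
#' @param flavors `flavor_table`.
#' @param substance substance name (case-insensitive).
#' @param jar_a,jar_b jar ids (change is relative to `jar_a`).
#' @param month observation month.
#' @return list of class `jar_contrast`: `substance`, `jar_a`, `jar_b`,
#'   `month`, `c_a`, `c_b`, `pct_change` (NA with `undefined_baseline = TRUE`
#'   when `c_a` is 0).
#' @export
jar_contrast <- function(flavors, substance, jar_a, jar_b, month) {
  sel <- tolower(flavors$substance) ==
    tolower(normalize_substance(substance)) & flavors$month == month
  ca <- flavors$mg_per_l[sel & flavors$jar_id == jar_a]
  cb <- flavors$mg_per_l[sel & flavors$jar_id == jar_b]
  if (length(ca) == 0 || length(cb) == 0)
    jf_stop("jf_validation_error",
            "no observation for '%s' at month %d in jar %d and/or %d",
            substance, month, jar_a, jar_b)
  c_a <- mean(ca); c_b <- mean(cb)
  undef <- c_a == 0
  structure(list(substance = substance, jar_a = jar_a, jar_b = jar_b,
                 month = month, c_a = c_a, c_b = c_b,
                 pct_change = if (undef) NA_real_ else 100 * (c_b - c_a) / c_a,
                 undefined_baseline = undef),
            class = "jar_contrast")
}

#' Correlation edge list between two variable blocks
#'
#' Pearson correlation of every column of `A` against every column of `B`,
#' with t-based p-values and significance markers.
#'
#' @param A,B numeric matrices with column names (rows aligned).
#' @param scheme marker scheme for [star_marks()].
#' @param source_tier,target_tier tier labels attached to the edges
#'   (`"jar_parameter"`, `"ion"`, `"flavor"`).
#' @return data.frame: source, target, source_tier, target_tier, r, p, stars,
#'   sign.
#' @export
correlation_edges <- function(A, B, scheme = "standard",
                              source_tier = "ion", target_tier = "flavor") {
  A <- as.matrix(A); B <- as.matrix(B)
  rows <- list()
  for (i in colnames(A)) for (j in colnames(B)) {
    if (stats::sd(A[, i]) == 0 || stats::sd(B[, j]) == 0) next
    pw <- pearson_with_p(A[, i], B[, j])
    rows[[length(rows) + 1]] <- data.frame(
      source = i, target = j,
      source_tier = source_tier, target_tier = target_tier,
      r = pw$r, p = pw$p, stars = star_marks(pw$p, scheme),
      sign = ifelse(pw$r >= 0, "positive", "negative"))
  }
  do.call(rbind, rows)
}

#' Partial correlations of jar parameters vs aged ion concentrations
#'
#' For each (jar parameter, ion) pair, correlates the parameter with the
#' ion's concentration at `target_month` across jars, controlling for that
#' same ion's concentrations at the `control_months` (the per-ion reading of
#' "earlier time points as control variables"). Replicates are averaged
#' within jar so the unit of analysis is the jar.
#'
#' @param dataset `study_dataset`.
#' @param target_month month of the correlated ion value (default 20).
#' @param control_months months supplying controls (default c(12, 16)).
#' @return edge data.frame as in [correlation_edges()], `partial` scheme.
#' @export
jar_ion_partial_edges <- function(dataset, target_month = 20L,
                                  control_months = c(12L, 16L)) {
  ions <- dataset$ions
  jars <- dataset$jars
  jar_means <- function(month)
    do.call(rbind, lapply(jars$jar_id, function(j)
      colMeans(ions[ions$jar_id == j & ions$month == month, ION_NAMES,
                    drop = FALSE])))
  tgt <- jar_means(target_month)
  ctl <- lapply(control_months, jar_means)
  params <- c("cu", "fe", "zn", "p_max", "p_min")
  param_label <- c(cu = "jar_Cu", fe = "jar_Fe", zn = "jar_Zn",
                   p_max = "P-max", p_min = "P-min")
  rows <- list()
  for (pp in params) for (ion in ION_NAMES) {
    C <- do.call(cbind, lapply(ctl, function(m) m[, ion]))
    keep <- qr(cbind(1, C))$rank == ncol(C) + 1
    x <- jars[[pp]]; y <- tgt[, ion]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    pc <- tryCatch(partial_correlation(x, y, if (keep) C else NULL),
                   jarflavor_error = function(e) NULL)
    if (is.null(pc)) next
    rows[[length(rows) + 1]] <- data.frame(
      source = param_label[[pp]], target = ion,
      source_tier = "jar_parameter", target_tier = "ion",
      r = pc$r, p = pc$p, stars = star_marks(pc$p, "partial"),
      sign = ifelse(pc$r >= 0, "positive", "negative"))
  }
  do.call(rbind, rows)
}

#' Build the tripartite correlation network
#'
#' Nodes are jar parameters, ions and flavor substances (tier attribute);
#' edges are the supplied correlations filtered at `p <= p_threshold`, with
#' weight `|r|` and a sign attribute (positive = solid, negative = dashed in
#' the conventional rendering).
#'
#' @param jar_ion_edges,ion_flavor_edges edge data.frames (see
#'   [correlation_edges()]).
#' @param p_threshold retain edges with `p <= p_threshold` (default 0.05).
#' @return `igraph` graph.
#' @export
build_network <- function(jar_ion_edges, ion_flavor_edges, p_threshold = 0.05) {
  edges <- rbind(jar_ion_edges, ion_flavor_edges)
  need <- c("source", "target", "source_tier", "target_tier", "r", "p")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    jf_stop("jf_validation_error", "edge table missing column(s): %s",
            paste(miss, collapse = ", "))
  tiers <- c("jar_parameter", "ion", "flavor")
  badt <- setdiff(unique(c(edges$source_tier, edges$target_tier)), tiers)
  if (length(badt))
    jf_stop("jf_validation_error", "unknown node tier(s): %s",
            paste(badt, collapse = ", "))
  nodes <- unique(rbind(
    data.frame(name = edges$source, tier = edges$source_tier),
    data.frame(name = edges$target, tier = edges$target_tier)))
  if (anyDuplicated(nodes$name))
    jf_stop("jf_validation_error", "node assigned to more than one tier")
  keep <- edges$p <= p_threshold
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source[keep], to = edges$target[keep],
               weight = abs(edges$r[keep]), r = edges$r[keep],
               p = edges$p[keep],
               sign = ifelse(edges$r[keep] >= 0, "positive", "negative")),
    directed = FALSE, vertices = nodes)
  g
}

#' Export a network as GraphML
#'
#' @param graph `igraph` graph from [build_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
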