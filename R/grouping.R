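#' Standardize flavor trajectories for clustering
#'
#' Builds the substances x conditions matrix (conditions ordered by
#' jar, replicate, month) and z-scores each substance row to mean 0, sd 1
#' (population sd), so clustering compares trajectory *shapes* rather than
#' absolute concentrations. Constant rows map to all-zeros with a warning.
#'
#' @param flavors `flavor_table` whose substances share one key grid.
#' @return numeric matrix, rownames = substances, colnames = `jar.rep.month`.
#' @export
standardize_trajectories <- function(flavors) {
  subs <- flavor_substances(flavors)
  key <- paste(flavors$jar_id, flavors$replicate, flavors$month, sep = ".")
  grid <- unique(data.frame(jar_id = flavors$jar_id,
                            replicate = flavors$replicate,
                            month = flavors$month, key = key))
  grid <- grid[order(grid$jar_id, grid$replicate, grid$month), ]
  M <- matrix(NA_real_, length(subs), nrow(grid),
              dimnames = list(subs, grid$key))
  for (s in subs) {
    rows <- flavors[flavors$substance == s, ]
    idx <- match(paste(rows$jar_id, rows$replicate, rows$month, sep = "."),
                 grid$key)
    M[s, idx] <- rows$mg_per_l
  }
  if (anyNA(M))
    jf_stop("jf_alignment_error",
            "substances do not share a common (jar, replicate, month) grid")
  n <- ncol(M)
  const <- logical(length(subs))
  for (i in seq_len(nrow(M))) {
    mu <- mean(M[i, ])
    sdp <- sqrt(mean((M[i, ] - mu)^2))  # population sd
    if (sdp == 0) {
      M[i, ] <- 0
      const[i] <- TRUE
    } else {
      M[i, ] <- (M[i, ] - mu) / sdp
    }
  }
  if (any(const))
    warning(sprintf("constant trajectory mapped to zeros: %s",
                    paste(subs[const], collapse = ", ")))
  M
}

# squared Euclidean distances of rows of M to rows of C
row_dist2 <- function(M, C) {
  outer(rowSums(M^2), rowSums(C^2), "+") - 2 * M %*% t(C)
}

kmeanspp_init <- function(M, k) {
  n <- nrow(M)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- row_dist2(M, M[centers[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      # remaining points coincide with chosen centers; pick any unused point
      pool <- setdiff(seq_len(n), centers[seq_len(j)])
      centers[j + 1] <- pool[sample.int(length(pool), 1)]
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = pmax(d2, 0))
    }
    d2 <- pmin(d2, row_dist2(M, M[centers[j + 1], , drop = FALSE])[, 1])
  }
  M[centers, , drop = FALSE]
}

lloyd <- function(M, C, iter_max = 100) {
  k <- nrow(C)
  labels_old <- rep(0L, nrow(M))
  for (it in seq_len(iter_max)) {
    D2 <- row_dist2(M, C)
    labels <- max.col(-D2, ties.method = "first")
    # re-seed empty clusters at the point farthest from its centroid
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.max(D2[cbind(seq_len(nrow(M)), labels)])
      labels[far] <- j
      D2[far, ] <- Inf; D2[far, j] <- 0
    }
    if (identical(labels, labels_old)) break
    labels_old <- labels
    for (j in seq_len(k)) {
      rows <- which(labels == j)
      if (length(rows))  # empty cluster keeps its previous center
        C[j, ] <- colMeans(M[rows, , drop = FALSE])
    }
  }
  wss <- sum((M - C[labels, , drop = FALSE])^2)
  list(labels = labels, centers = C, wss = wss)
}

#' K-means clustering of standardized trajectories
#'
#' Lloyd iterations from k-means++ starts, best of `n_init` restarts by
#' within-cluster sum of squares; fully seeded and reproducible. k is a user
#' parameter (the study used 10); no automatic selection is attempted.
#'
#' @param M standardized matrix from [standardize_trajectories()].
#' @param k number of clusters (<= nrow(M)).
#' @param seed integer seed.
#' @param n_init number of restarts (default 50).
#' @return list of class `flavor_grouping`: `k`, `labels` (named integer
#'   vector), `centroids` (k x conditions), `wss`, and empty `representatives`
#'   (filled by [group_flavors()]).
#' @export
kmeans_cluster <- function(M, k, seed = 1L, n_init = 50L) {
  if (k > nrow(M))
    jf_stop("jf_parameter_error", "k = %d exceeds %d substances", k, nrow(M))
  if (!all(is.finite(M)))
    jf_stop("jf_validation_error", "non-finite values in trajectory matrix")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(M, kmeanspp_init(M, k))
      if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
    }
  })
  labels <- stats::setNames(best$labels, rownames(M))
  structure(list(k = k, labels = labels, centroids = best$centers,
                 wss = best$wss, representatives = list()),
            class = "flavor_grouping")
}

#' Representatives to pick for a group of a given size
#'
#' The study's size rule: 1 representative for groups of at most 5
#' substances, 2 for sizes 6-10, 3 above 10. (The printed bands omit size 10
#' exactly; it is assigned to the 2-representative band for continuity.)
#'
#' @param group_size integer >= 1.
#' @return 1, 2 or 3.
#' @export
representative_count <- function(group_size) {
  if (any(group_size < 1))
    jf_stop("jf_parameter_error", "group size must be >= 1")
  ifelse(group_size <= 5, 1L, ifelse(group_size <= 10, 2L, 3L))
}

#' Pick the members closest to the group centroid
#'
#' Representatives are the `count` members whose standardized trajectories
#' correlate most strongly (Pearson) with the group centroid; ties break
#' alphabetically, so zero-noise groups (all members identical after
#' z-scoring) yield the alphabetically first members.
#'
#' @param members character vector of substance names in the group.
#' @param M standardized trajectory matrix.
#' @param centroid numeric centroid trajectory.
#' @param count number of representatives (<= group size).
#' @return ordered character vector of length `count`.
#' @export
select_representatives <- function(members, M, centroid, count) {
  if (count > length(members))
    jf_stop("jf_parameter_error", "count exceeds group size")
  r <- vapply(members, function(s) {
    v <- M[s, ]
    if (stats::sd(v) == 0 || stats::sd(centroid) == 0) return(-Inf)
    stats::cor(v, centroid)
  }, numeric(1))
  members[order(-r, members)][seq_len(count)]
}

#' Cluster a flavor table and choose representatives
#'
#' Convenience wrapper: standardize, cluster with k-means, then apply the
#' size rule and centroid-correlation criterion per group.
#'
#' @param flavors `flavor_table`.
#' @param k number of groups (default 10).
#' @param seed integer seed.
#' @param n_init restarts (default 50).
#' @return `flavor_grouping` with `representatives` filled (one ordered
#'   character vector per group).
#' @export
group_flavors <- function(flavors, k = 10L, seed = 1L, n_init = 50L) {
  M <- standardize_trajectories(flavors)
  g <- kmeans_cluster(M, k, seed = seed, n_init = n_init)
  g$representatives <- lapply(seq_len(k), function(j) {
    members <- names(g$labels)[g$labels == j]
    select_representatives(members, M, g$centroids[j, ],
                           representative_count(length(members)))
  })
  names(g$representatives) <- paste0("G", seq_len(k))
  g
}

#' @export
print.flavor_grouping <- function(x, ...) {
  sizes <- tabulate(x$labels, x$k)
  cat("flavor_grouping: k =", x$k, "; sizes:", paste(sizes, collapse = ", "),
      "\nrepresentatives:", sum(lengths(x$representatives)), "\n")
  invisible(x)
}
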