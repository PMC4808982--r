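# Agglomerative clustering with correlation distance and average linkage.
#
# Implemented directly (rather than through stats::hclust) because the
# assignment contract requires bit-for-bit determinism under input
# permutation: ties in merge height are broken lexicographically by the
# smallest entity id contained in each candidate cluster, and entities are
# canonically sorted before any distance is computed.

# average-linkage agglomeration over a distance matrix; returns an
# hclust-compatible structure (merge, height, order, labels)
hac_average <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2L) {
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          order = seq_len(n), labels = labels,
                          method = "average", dist.method = "correlation"),
                     class = "hclust"))
  }
  d <- D
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  rep_id <- labels                 # lexicographically smallest member id
  node <- -seq_len(n)              # hclust merge coding
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  order_list <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    h <- min(dm)
    cand <- which(dm == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on the (sorted) pair of representative ids
    key1 <- pmin(rep_id[cand[, 1]], rep_id[cand[, 2]])
    key2 <- pmax(rep_id[cand[, 1]], rep_id[cand[, 2]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- h
    # average-linkage Lance-Williams update into slot i
    others <- which(active)
    others <- others[others != i & others != j]
    if (length(others) > 0) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    node[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    order_list[[i]] <- c(order_list[[i]], order_list[[j]])
  }
  structure(list(merge = merge, height = height,
                 order = order_list[[which(active)]], labels = labels,
                 method = "average", dist.method = "correlation"),
            class = "hclust")
}

correlation_distance <- function(m) {
  D <- 1 - cor(t(m))
  D[D < 0] <- 0                    # clamp -1e-16 artefacts
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

# mean silhouette width for a labelled partition over a distance matrix
mean_silhouette <- function(D, labels) {
  n <- length(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cluster unit and station profiles by temporal similarity
#'
#' Groups spatial units and monitoring stations whose standardized annual
#' concentration profiles co-vary, using hierarchical agglomerative
#' clustering with correlation distance (1 minus the Pearson correlation of
#' profiles) and average linkage. The dendrogram is deterministic under any
#' permutation of the input rows: entities are sorted canonically and merge
#' ties are broken lexicographically.
#'
#' @param features A `"series_features"` tibble from [build_features()].
#' @param k Number of clusters to cut, or `"auto"` (default) to choose the
#'   k in `2..min(10, n - 1)` with the largest mean silhouette width
#'   (smallest k on ties).
#' @return A list of class `"station_clustering"`: `labels` (tibble
#'   `entity_id`, `kind`, `cluster`), `k`, `silhouette` (mean width of the
#'   chosen cut), `hclust` (the merge tree, an [stats::hclust] object), and
#'   `dist` (the correlation-distance matrix). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @seealso [assign_index()] for choosing each unit's index monitor.
#' @export
cluster_profiles <- function(features, k = "auto") {
  m <- feature_matrix(features)
  n <- nrow(m)
  kinds <- features |>
    dplyr::distinct(.data$entity_id, .data$kind) |>
    dplyr::arrange(.data$entity_id)
  D <- correlation_distance(m)
  tree <- hac_average(D)

  if (identical(k, "auto")) {
    ks <- 2:min(10L, n - 1L)
    if (length(ks) == 0L || n < 3L) {
      k <- max(1L, n - 1L)
    } else {
      sil <- vapply(ks, function(kk) mean_silhouette(D, cutree(tree, kk)),
                    numeric(1))
      k <- ks[which.max(sil)]     # which.max: smallest k on ties
    }
  }
  if (!is_count(k) || k < 1L || k > n) {
    stop_cumulair(sprintf("k must be an integer in 1..%d or \"auto\"", n),
                  "cumulair_config_error")
  }
  cl <- cutree(tree, k)
  labels <- tibble::tibble(entity_id = rownames(m),
                           cluster = as.integer(cl)) |>
    dplyr::left_join(kinds, by = "entity_id") |>
    dplyr::select("entity_id", "kind", "cluster")

  orphans <- labels |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(!any(.data$kind == "station") & any(.data$kind == "unit")) |>
    dplyr::ungroup()
  if (nrow(orphans) > 0L && any(labels$kind == "station")) {
    warn(sprintf(
      "cluster(s) without any monitoring station; orphan unit(s): %s",
      paste(orphans$entity_id[orphans$kind == "unit"], collapse = ", ")))
  }

  structure(list(labels = labels, k = as.integer(k),
                 silhouette = if (k > 1L && k < n) mean_silhouette(D, cl) else NA_real_,
                 hclust = tree, dist = D),
            class = "station_clustering")
}

#' @export
print.station_clustering <- function(x, ...) {
  cat(sprintf("<station_clustering> %d entities in %d clusters\n",
              nrow(x$labels), x$k))
  print(dplyr::count(x$labels, .data$cluster, .data$kind))
  invisible(x)
}

#' Export the merge tree as a plain-text dendrogram table
#'
#' @param clustering A `"station_clustering"` object.
#' @return A tibble with one row per merge: `step`, `height`, and the
#'   member entity ids of the two merged groups (collapsed with `"+"`).
#' @export
dendrogram_table <- function(clustering) {
  tree <- clustering$hclust
  n <- length(tree$labels)
  members <- vector("list", nrow(tree$merge))
  get_members <- function(id) {
    if (id < 0) tree$labels[-id] else members[[id]]
  }
  out <- purrr::map(seq_len(nrow(tree$merge)), function(s) {
    a <- get_members(tree$merge[s, 1])
    b <- get_members(tree$merge[s, 2])
    members[[s]] <<- c(a, b)
    tibble::tibble(step = s, height = tree$height[s],
                   group_a = paste(sort(a), collapse = "+"),
                   group_b = paste(sort(b), collapse = "+"))
  })
  dplyr::bind_rows(out)
}

#' Assign each unit its index monitoring station
#'
#' Within each cluster, every unit is mapped to the spatially nearest
#' (Euclidean) monitoring station of the same cluster — its "index"
#' monitor, taken to best represent the unit's pollutant time variability.
#' Exact distance ties are resolved by lexicographically smallest
#' `station_id` and reported via a message.
#'
#' @param clustering A `"station_clustering"` from [cluster_profiles()].
#' @param units Unit registry tibble (`unit_id`, `x`, `y`).
#' @param stations Station registry tibble (`station_id`, `x`, `y`).
#' @return A tibble (`unit_id`, `station_id`, `cluster`, `distance`) with
#'   one row per clustered unit.
#' @export
assign_index <- function(clustering, units, stations) {
  labels <- clustering$labels
  unit_lab <- dplyr::filter(labels, .data$kind == "unit")
  stat_lab <- dplyr::filter(labels, .data$kind == "station")
  orphan <- unit_lab$entity_id[!unit_lab$cluster %in% stat_lab$cluster]
  if (length(orphan) > 0L) {
    stop_cumulair(
      sprintf("cluster(s) contain units but no station; orphan unit(s): %s",
              paste(orphan, collapse = ", ")),
      "cumulair_assignment_error")
  }
  u <- dplyr::inner_join(unit_lab, units,
                         by = c(entity_id = "unit_id"))
  s <- dplyr::inner_join(stat_lab, stations,
                         by = c(entity_id = "station_id"))
  out <- purrr::pmap(u, function(entity_id, kind, cluster, x, y, ...) {
    cand <- s[s$cluster == cluster, ]
    dd <- sqrt((cand$x - x)^2 + (cand$y - y)^2)
    ord <- order(dd, cand$entity_id)
    if (length(ord) > 1L && dd[ord[1]] == dd[ord[2]]) {
      rlang::inform(sprintf(
        "unit %s equidistant from stations %s and %s; choosing %s",
        entity_id, cand$entity_id[ord[1]], cand$entity_id[ord[2]],
        cand$entity_id[ord[1]]))
    }
    tibble::tibble(unit_id = entity_id,
                   station_id = cand$entity_id[ord[1]],
                   cluster = cluster, distance = dd[ord[1]])
  })
  dplyr::bind_rows(out)
}
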