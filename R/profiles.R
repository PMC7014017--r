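#' Encode a census as a presence/absence matrix
#'
#' Heat-map convention for family profiles: a species-by-family matrix
#' with 3 where the family is present (census count > 0) and -3 where it
#' is absent. The signed encoding keeps present/absent visually symmetric
#' around zero in heat-map software.
#'
#' @param census a [build_census()] result.
#' @return integer matrix of 3 / -3 with the census dimnames.
#' @export
encode_presence <- function(census) {
  stopifnot(inherits(census, "census_table"))
  m <- census$family
  out <- matrix(ifelse(m > 0, 3L, -3L), nrow(m), ncol(m),
                dimnames = dimnames(m))
  out
}

# Deterministic agglomerative clustering. stats::hclust is not used
# because run-to-run reproducibility here requires a pinned tie-break:
# among all minimum-distance cluster pairs, merge the one whose combined
# sorted label set is lexicographically smallest. Between-cluster
# distances are maintained with Lance-Williams updates (average linkage
# is UPGMA: d(ab,i) = (na*d(a,i) + nb*d(b,i)) / (na+nb)).
#' @noRd
agglomerate <- function(d, labels, linkage) {
  n <- length(labels)
  clusters <- lapply(seq_len(n), identity)   # member indices
  keys <- labels                             # "\r"-joined sorted labels
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  nodes <- as.list(labels)                   # newick fragments
  merges <- list()
  active <- seq_len(n)
  D <- rbind(cbind(d, matrix(NA_real_, n, n - 1L)),
             matrix(NA_real_, n - 1L, 2L * n - 1L))
  step <- 0L
  while (length(active) > 1L) {
    best <- NULL
    for (i in seq_along(active)[-length(active)]) {
      for (j in seq((i + 1L), length(active))) {
        a <- active[i]; b <- active[j]
        dv <- D[a, b]
        key <- paste(sort(c(strsplit(keys[a], "\r", fixed = TRUE)[[1]],
                            strsplit(keys[b], "\r", fixed = TRUE)[[1]])),
                     collapse = "\r")
        if (is.null(best) || dv < best$d - 1e-12 ||
            (abs(dv - best$d) <= 1e-12 && key < best$key)) {
          best <- list(a = a, b = b, d = dv, key = key)
        }
      }
    }
    step <- step + 1L
    a <- best$a; b <- best$b
    new_id <- n + step
    clusters[[new_id]] <- c(clusters[[a]], clusters[[b]])
    keys[new_id] <- best$key
    sizes[new_id] <- sizes[a] + sizes[b]
    heights[new_id] <- best$d
    active <- setdiff(active, c(a, b))
    for (x in active) {
      D[new_id, x] <- D[x, new_id] <- switch(linkage,
        single = min(D[a, x], D[b, x]),
        complete = max(D[a, x], D[b, x]),
        average = (sizes[a] * D[a, x] + sizes[b] * D[b, x]) /
          (sizes[a] + sizes[b]))
    }
    # children ordered by key so the newick string is canonical
    kids <- c(a, b)[order(c(keys[a], keys[b]))]
    nodes[[new_id]] <- paste0(
      "(", nodes[[kids[1]]], ":",
      format(max(heights[new_id] - heights[kids[1]], 0), digits = 12),
      ",", nodes[[kids[2]]], ":",
      format(max(heights[new_id] - heights[kids[2]], 0), digits = 12), ")")
    merges[[step]] <- data.frame(
      step = step,
      cluster_a = paste(labels[clusters[[kids[1]]]], collapse = ","),
      cluster_b = paste(labels[clusters[[kids[2]]]], collapse = ","),
      height = best$d,
      stringsAsFactors = FALSE)
    active <- c(active, new_id)
  }
  root <- active[1L]
  list(order = labels[clusters[[root]]],
       merges = do.call(rbind, merges),
       newick = paste0(nodes[[root]], ";"),
       height = heights[root])
}

#' Hierarchically cluster a presence/absence matrix
#'
#' Agglomerative clustering of rows and columns under a Euclidean metric,
#' for heat-map row/column ordering. The implementation is deterministic:
#' among equally close cluster pairs the one with the lexicographically
#' smallest combined label set is merged first, so identical inputs always
#' give identical dendrograms regardless of row order.
#'
#' @param m numeric matrix with row and column names (typically from
#'   [encode_presence()]).
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @return list with `rows` and `cols`, each containing `order` (leaf
#'   order), `merges` (merge sequence with heights) and `newick`
#'   (dendrogram with branch lengths = merge-height differences).
#' @export
hierarchical_cluster <- function(m, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  one_axis <- function(x) {
    if (nrow(x) < 2L) {
      warning("fewer than 2 items; returning identity ordering")
      return(list(order = rownames(x), merges = NULL,
                  newick = paste0(rownames(x), ";")))
    }
    d <- as.matrix(stats::dist(x, method = "euclidean"))
    agglomerate(d, rownames(x), linkage)
  }
  list(rows = one_axis(m), cols = one_axis(t(m)))
}

#' Export a clustered heat-map matrix as TSV
#'
#' Writes the matrix with rows and columns permuted into dendrogram leaf
#' order; entries keep the 3 / -3 presence encoding. Output is bit-exact
#' across runs.
#'
#' @param m matrix from [encode_presence()].
#' @param orders result of [hierarchical_cluster()] on `m`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(m, orders, path) {
  ro <- orders$rows$order
  co <- orders$cols$order
  stopifnot(setequal(ro, rownames(m)), setequal(co, colnames(m)))
  mm <- m[ro, co, drop = FALSE]
  df <- data.frame(id = rownames(mm), mm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Read back an exported heat-map TSV
#' @param path TSV written by [export_heatmap()].
#' @return integer matrix with row/column names.
#' @export
read_heatmap <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "integer"
  m
}
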