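# Cohort reconstruction: mutations whose population frequencies move
# together through time are inferred to be linked on one background and
# are grouped into "cohorts" (haplotypes) by hierarchical clustering of
# their frequency trajectories.

#' Build a complete trajectory matrix
#'
#' Extracts the frequency matrix from a trajectory table and fills missing
#' values: interior gaps are linearly interpolated on the generation axis,
#' leading missing values become 0 (the mutation had not been seen yet)
#' and trailing missing values carry the last observation forward.
#'
#' @param records Trajectory data.frame.
#' @return Numeric matrix (rows = mutation ids, columns = `g<generation>`),
#'   with an `imputed` attribute marking filled cells.
#' @export
trajectory_matrix <- function(records) {
  fc <- freq_cols(records)
  m <- as.matrix(records[, fc, drop = FALSE])
  rownames(m) <- as.character(records$id)
  gens <- traj_generations(records)
  imputed <- is.na(m)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (!anyNA(v)) next
    obs <- which(!is.na(v))
    if (!length(obs)) stop("row ", rownames(m)[i],
                           " has no observed frequency", call. = FALSE)
    first <- min(obs); last <- max(obs)
    if (first > 1) v[seq_len(first - 1)] <- 0
    if (last < length(v)) v[(last + 1):length(v)] <- v[last]
    gap <- which(is.na(v))
    if (length(gap))
      v[gap] <- stats::approx(gens[!is.na(v)], v[!is.na(v)],
                              xout = gens[gap])$y
    m[i, ] <- v
  }
  attr(m, "imputed") <- imputed
  m
}

#' Cluster trajectories into linked-mutation cohorts
#'
#' Agglomerative clustering (complete linkage) on the Euclidean distance
#' between frequency trajectories, cut at `distance_threshold`: every pair
#' of mutations within a cohort has trajectory distance at most the
#' threshold, the "moves together" reading of linkage. The cohort
#' trajectory is the arithmetic mean of its members' rows.
#'
#' @param m Complete trajectory matrix (see [trajectory_matrix()]).
#' @param distance_threshold Cut height (> 0); default 0.3.
#' @return A `cohort_set` list: `cohorts` (list of member-id character
#'   vectors), `trajectories` (cohorts x generations mean matrix),
#'   `origin` (first generation with mean frequency > 0), `labels`,
#'   and the `generations`. Cohorts are ordered by origin generation, then
#'   label.
#' @export
cluster_trajectories <- function(m, distance_threshold = 0.3) {
  stopifnot(is.matrix(m), !anyNA(m), distance_threshold > 0)
  gens <- as.numeric(sub("^g", "", colnames(m)))
  if (nrow(m) == 1) {
    memb <- stats::setNames(1L, rownames(m))
  } else {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    memb <- stats::cutree(hc, h = distance_threshold)
  }
  groups <- split(names(memb), memb)
  traj <- t(vapply(groups, function(ids)
    colMeans(m[ids, , drop = FALSE]), numeric(ncol(m))))
  origin <- apply(traj, 1, function(f) {
    i <- which(f > 0)
    if (length(i)) gens[min(i)] else Inf
  })
  ord <- order(origin, vapply(groups, function(g) min(g), ""))
  groups <- groups[ord]
  traj <- traj[ord, , drop = FALSE]
  origin <- origin[ord]
  labels <- sprintf("C%02d", seq_along(groups))
  names(groups) <- rownames(traj) <- names(origin) <- labels
  out <- list(cohorts = groups, trajectories = traj, origin = origin,
              labels = labels, generations = gens)
  class(out) <- "cohort_set"
  out
}

#' Clonal-interference statistics
#'
#' Flags, for each mutation trajectory, extinction (observed above zero at
#' some generation but at zero at the final sequenced generation) and
#' decline (frequency drops by more than `drop` below its running maximum
#' at any later observation — mutations partly or wholly outcompeted after
#' reaching their peak). Both flags can co-occur.
#'
#' @param m Complete trajectory matrix.
#' @param drop Decline threshold (default 0.10, strict).
#' @return List `n_total`, `n_extinct`, `n_decliners`, and a data.frame
#'   `flags` (id, extinct, decliner, max_freq, final_freq).
#' @export
clonal_interference_stats <- function(m, drop = 0.10) {
  stopifnot(is.matrix(m), !anyNA(m))
  final <- m[, ncol(m)]
  extinct <- apply(m, 1, function(f) any(f > 0)) & final == 0
  drawdown <- apply(m, 1, function(f) max(cummax(f) - f))
  decliner <- drawdown > drop + 1e-9   # strict, floating-point safe
  flags <- data.frame(
    id = rownames(m),
    extinct = unname(extinct),
    decliner = unname(decliner),
    max_freq = unname(apply(m, 1, max)),
    final_freq = unname(final),
    stringsAsFactors = FALSE
  )
  list(n_total = nrow(m),
       n_extinct = sum(extinct),
       n_decliners = sum(decliner),
       flags = flags)
}
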