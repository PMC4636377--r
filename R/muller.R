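# Muller-diagram reconstruction: cohorts are arranged in a nesting forest
# where a cohort's parent is the genetic background on which it arose,
# inferred from frequency containment.

#' Build a Muller nesting structure over cohorts
#'
#' A cohort B is eligible to nest inside cohort A when A originated no
#' later than B and `freq_B(t) <= freq_A(t) + epsilon` at every generation
#' where B is present (a descendant can never outnumber the lineage it
#' arose on, up to measurement noise). Among eligible parents the one with
#' the smallest mean frequency excess over B is chosen (the tightest
#' containing background). Cohorts with no eligible parent are top-level;
#' the residual ancestral fraction per generation is one minus the summed
#' top-level frequencies.
#'
#' @param cohorts A `cohort_set` from [cluster_trajectories()].
#' @param epsilon Containment tolerance (default 0.02, roughly twice the
#'   binomial standard error of a 10% allele at 500x depth).
#' @return A `muller_diagram` list: `parent` (named vector, NA for
#'   top-level), `trajectories`, `residual` (ancestral fraction per
#'   generation), `generations`, `cohorts`, `warnings` (cohorts whose best
#'   candidate violated containment beyond epsilon and were forced
#'   top-level).
#' @export
build_muller <- function(cohorts, epsilon = 0.02) {
  stopifnot(inherits(cohorts, "cohort_set"))
  traj <- cohorts$trajectories
  origin <- cohorts$origin
  n <- nrow(traj)
  parent <- stats::setNames(rep(NA_character_, n), rownames(traj))
  warn <- character(0)
  for (b in seq_len(n)) {
    present <- traj[b, ] > 0
    cand <- setdiff(which(origin <= origin[b]), b)
    # origin ties broken toward earlier-labelled (earlier-origin-sorted)
    cand <- cand[cand < b | origin[cand] < origin[b]]
    if (!length(cand)) next
    # mean frequency excess of eligible parents
    excess <- vapply(cand, function(a) {
      d <- traj[a, present] - traj[b, present]
      if (all(d >= -epsilon)) mean(d) else NA_real_
    }, numeric(1))
    if (all(is.na(excess))) {
      if (any(vapply(cand, function(a)
        any(traj[a, present] < traj[b, present] - epsilon), logical(1))))
        warn <- c(warn, rownames(traj)[b])
      next
    }
    parent[b] <- rownames(traj)[cand[which.min(excess)]]
  }
  top <- which(is.na(parent))
  residual <- 1 - colSums(traj[top, , drop = FALSE])
  out <- list(parent = parent, trajectories = traj, residual = residual,
              generations = cohorts$generations, cohorts = cohorts$cohorts,
              warnings = warn)
  class(out) <- "muller_diagram"
  if (length(warn))
    warning("containment violated beyond epsilon for: ",
            paste(warn, collapse = ", "), "; forced top-level",
            call. = FALSE)
  out
}

#' Export / import a Muller diagram
#'
#' `export_muller()` writes a machine-readable JSON document (cohorts,
#' members, parents, per-generation frequencies, residual) and, optionally,
#' a long-format tab-separated table (`cohort`, `parent`, `generation`,
#' `frequency`) suitable for stacked-area plotting. `read_muller()` reads
#' the JSON back.
#'
#' @param diagram A `muller_diagram`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional long-format TSV path.
#' @return `export_muller()`: `json_path`, invisibly. `read_muller()`: a
#'   `muller_diagram`.
#' @export
export_muller <- function(diagram, json_path, tsv_path = NULL) {
  stopifnot(inherits(diagram, "muller_diagram"))
  doc <- list(
    generations = diagram$generations,
    residual = unname(diagram$residual),
    cohorts = lapply(names(diagram$parent), function(lab) {
      list(label = lab,
           parent = diagram$parent[[lab]],
           members = as.character(diagram$cohorts[[lab]]),
           frequencies = unname(diagram$trajectories[lab, ]))
    })
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(tsv_path)) {
    long <- do.call(rbind, lapply(names(diagram$parent), function(lab)
      data.frame(cohort = lab,
                 parent = ifelse(is.na(diagram$parent[[lab]]), "",
                                 diagram$parent[[lab]]),
                 generation = diagram$generations,
                 frequency = unname(diagram$trajectories[lab, ]),
                 stringsAsFactors = FALSE)))
    if (is.null(long))
      long <- data.frame(cohort = character(), parent = character(),
                         generation = numeric(), frequency = numeric())
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}

#' @rdname export_muller
#' @export
read_muller <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  gens <- as.numeric(unlist(doc$generations))
  labs <- vapply(doc$cohorts, function(x) x$label, "")
  traj <- matrix(0, length(labs), length(gens),
                 dimnames = list(labs, paste0("g", gens)))
  parent <- stats::setNames(rep(NA_character_, length(labs)), labs)
  cohorts <- stats::setNames(vector("list", length(labs)), labs)
  for (x in doc$cohorts) {
    traj[x$label, ] <- as.numeric(unlist(x$frequencies))
    parent[x$label] <- if (is.null(x$parent)) NA_character_ else x$parent
    cohorts[[x$label]] <- as.character(unlist(x$members))
  }
  out <- list(parent = parent, trajectories = traj,
              residual = as.numeric(unlist(doc$residual)),
              generations = gens, cohorts = cohorts, warnings = character(0))
  class(out) <- "muller_diagram"
  out
}

#' Check Muller invariants
#'
#' Verifies that, at every generation, children frequencies sum to at most
#' their parent's frequency plus `epsilon`, and that the residual
#' ancestral fraction is at least `-epsilon`.
#'
#' @param diagram A `muller_diagram`.
#' @param epsilon Tolerance.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
check_muller <- function(diagram, epsilon = 0.02) {
  traj <- diagram$trajectories
  for (lab in names(diagram$parent)) {
    kids <- names(diagram$parent)[!is.na(diagram$parent) &
                                    diagram$parent == lab]
    if (!length(kids)) next
    tot <- colSums(traj[kids, , drop = FALSE])
    if (any(tot > traj[lab, ] + epsilon))
      stop("children of ", lab, " exceed parent frequency", call. = FALSE)
  }
  if (any(diagram$residual < -epsilon))
    stop("negative residual ancestral fraction", call. = FALSE)
  invisible(TRUE)
}

#' True cohort parentage from simulator truth
#'
#' Maps each inferred cohort to the lineage its members arose on and reads
#' the parent cohort off the true lineage tree: cohort A is the true
#' parent of cohort B when A's lineage is the nearest ancestor of B's
#' lineage that carries a clustered mutation.
#'
#' @param cohorts A `cohort_set` whose member ids are simulator mutation
#'   ids.
#' @param truth The `sim_truth`.
#' @return Named character vector of true parent labels (NA = top-level).
#' @export
true_parentage <- function(cohorts, truth) {
  mut2lin <- stats::setNames(truth$mutations$lineage,
                             as.character(truth$mutations$id))
  coh_lin <- vapply(cohorts$cohorts, function(ids) {
    lins <- unique(mut2lin[ids])
    # members of one cohort should share a background; take the deepest
    lins[which.max(vapply(lins, function(l)
      length(lineage_ancestry(truth, l)), numeric(1)))]
  }, numeric(1))
  lin2coh <- stats::setNames(names(coh_lin), coh_lin)
  out <- stats::setNames(rep(NA_character_, length(coh_lin)),
                         names(coh_lin))
  for (lab in names(coh_lin)) {
    anc <- rev(lineage_ancestry(truth, coh_lin[[lab]]))
    anc <- anc[-1]  # exclude own lineage
    hit <- anc[as.character(anc) %in% names(lin2coh)]
    if (length(hit)) out[lab] <- lin2coh[[as.character(hit[1])]]
  }
  out
}
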