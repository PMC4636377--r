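# Readers and writers for the tab-separated formats used throughout:
# variant trajectory tables, depth tracks, gene annotation, chromosome
# lengths, interaction networks (SIF-style) and gene lists.

#' Frequency columns of a trajectory table
#'
#' Trajectory tables carry one column per sequenced generation, named
#' `g<generation>` (e.g. `g0`, `g25`, ...).
#'
#' @param x A trajectory data.frame.
#' @return Character vector of frequency column names, ordered by
#'   generation.
#' @export
freq_cols <- function(x) {
  cols <- grep("^g[0-9]+$", names(x), value = TRUE)
  cols[order(as.numeric(sub("^g", "", cols)))]
}

#' Generations covered by a trajectory table
#' @param x A trajectory data.frame.
#' @return Numeric vector of generations.
#' @export
traj_generations <- function(x) as.numeric(sub("^g", "", freq_cols(x)))

#' Read / write a variant trajectory table
#'
#' Tab-separated, one row per variant: `id`, `chrom`, `pos`, `ref`, `alt`,
#' `class`, `gene`, then one `g<generation>` frequency column per sampled
#' generation (additional annotation columns pass through).
#'
#' @param path File path.
#' @return `read_trajectories`: a data.frame.
#' @export
read_trajectories <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!length(freq_cols(x)))
    stop("no g<generation> frequency columns found in ", path, call. = FALSE)
  x
}

#' @rdname read_trajectories
#' @param x Trajectory data.frame.
#' @export
write_trajectories <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant trajectories from a VCF
#'
#' Extracts per-sample allele frequencies from a multi-sample VCF in which
#' each sample is one sequenced time point. Frequencies come from the `AF`
#' FORMAT tag when present, otherwise from allelic depths (`AD`,
#' alt / (ref + alt)).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param generations Numeric vector mapping the VCF sample columns, in
#'   order, to generations.
#' @param af_tag,ad_tag FORMAT tag names to use.
#' @return A trajectory data.frame as from [read_trajectories()].
#' @export
read_trajectories_vcf <- function(path, generations,
                                  af_tag = "AF", ad_tag = "AD") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input needs the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_samp <- ncol(v@gt) - 1L
  if (length(generations) != n_samp)
    stop("VCF has ", n_samp, " samples but ", length(generations),
         " generations were given", call. = FALSE)
  af <- tryCatch(
    vcfR::extract.gt(v, element = af_tag, as.numeric = TRUE),
    error = function(e) NULL)
  if (is.null(af) || all(is.na(af))) {
    ad <- vcfR::extract.gt(v, element = ad_tag)
    ref <- as.numeric(vapply(strsplit(ad, ","), `[`, "", 1L))
    alt <- as.numeric(vapply(strsplit(ad, ","), `[`, "", 2L))
    af <- matrix(alt / (ref + alt), nrow = nrow(ad), ncol = ncol(ad))
  }
  out <- data.frame(
    id = if (all(fix$ID %in% c(NA, "."))) seq_len(nrow(fix)) else fix$ID,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    class = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                   "SNP", "indel"),
    gene = NA_character_, stringsAsFactors = FALSE
  )
  for (j in seq_along(generations))
    out[[paste0("g", generations[j])]] <- as.numeric(af[, j])
  out
}

#' Read / write a binned depth track
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `count` (optionally
#' `clone` first); bins are 0-based half-open.
#'
#' @param path File path.
#' @export
read_depth_track <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(x)))
    stop("depth track needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname read_depth_track
#' @param x Depth-track data.frame.
#' @export
write_depth_track <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome annotation
#'
#' @param gene_path BED-like tab-separated gene table with columns `gene`,
#'   `chrom`, `start`, `end` and optionally `coding_length` (defaults to
#'   the interval width).
#' @param length_path Two-column tab-separated table `chrom`, `length`.
#' @return Annotation list with `chrom_lengths`, `genes`,
#'   `total_coding_length` (the structure produced by [sim_genome()]).
#' @export
read_annotation <- function(gene_path, length_path) {
  genes <- utils::read.delim(gene_path, stringsAsFactors = FALSE)
  lens <- utils::read.delim(length_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "length") %in% names(lens)))
  if (is.null(genes$coding_length))
    genes$coding_length <- genes$end - genes$start + 1
  list(chrom_lengths = lens, genes = genes,
       total_coding_length = sum(genes$coding_length))
}

#' Read an interaction network edge list
#'
#' Accepts either a three-column tab-separated edge list
#' (`source`, `target`, `type`) or SIF order (`source`, `type`, `target`,
#' auto-detected when the middle column holds the known interaction
#' types). Protein-protein ("pp") edges are expanded to two directed arcs.
#'
#' @param path File path.
#' @param pp_types Interaction type labels treated as undirected.
#' @return data.frame `from`, `to`, `type` of directed arcs.
#' @export
read_network <- function(path, pp_types = c("pp", "protein-protein")) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("network file needs three columns", call. = FALSE)
  known <- c(pp_types, "metabolic", "protein-DNA", "pd", "met")
  if (all(x[[2]] %in% known) && !all(x[[3]] %in% known)) {
    edges <- data.frame(from = x[[1]], to = x[[3]], type = x[[2]],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = x[[1]], to = x[[2]], type = x[[3]],
                        stringsAsFactors = FALSE)
  }
  as_directed_edges(edges, pp_types)
}

#' Expand undirected protein-protein edges to directed arcs
#'
#' @param edges data.frame `from`, `to`, `type`.
#' @param pp_types Types treated as undirected.
#' @return data.frame of directed arcs with self-loops dropped and
#'   duplicates removed.
#' @export
as_directed_edges <- function(edges, pp_types = c("pp", "protein-protein")) {
  stopifnot(all(c("from", "to", "type") %in% names(edges)))
  und <- edges$type %in% pp_types
  out <- rbind(edges,
               data.frame(from = edges$to[und], to = edges$from[und],
                          type = edges$type[und], stringsAsFactors = FALSE))
  out <- out[out$from != out$to, , drop = FALSE]
  out <- out[!duplicated(out[, c("from", "to", "type")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a sub-network as a SIF edge list
#'
#' @param subnet A `subnetwork` from [select_subnetwork()].
#' @param path Output path.
#' @export
write_sif <- function(subnet, path) {
  e <- subnet$edges
  utils::write.table(data.frame(e$from, e$type, e$to), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one name per line)
#' @param path File path.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
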