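## Compositional (Aitchison simplex) geometry and complete-linkage
## clustering of expression profiles.

#' Close a TPM vector into a strictly positive composition
#'
#' Adds `pseudocount` to every part (zeros are pervasive in tag data
#' and log-ratio geometry requires strict positivity) and normalizes
#' to sum 1.
#'
#' @param tpm named nonnegative numeric vector (parts), not all zero.
#' @param pseudocount nonnegative value added to every part before
#'   closure (default 1).
#' @param id profile identifier.
#' @return A `composition`: list with `id`, `parts`, `prop`,
#'   `pseudocount`.
#' @export
to_composition <- function(tpm, pseudocount = 1, id = NULL) {
  stopifnot(is.numeric(tpm), all(tpm >= 0), pseudocount >= 0)
  if (sum(tpm) == 0) stop_fmt("to_composition(): all-zero vector")
  x <- tpm + pseudocount
  if (any(x == 0))
    stop_fmt("to_composition(): zero part with pseudocount 0; use a positive pseudocount")
  structure(list(id = id, parts = names(tpm), prop = unname(x / sum(x)),
                 pseudocount = pseudocount),
            class = "composition")
}

clr <- function(p) log(p) - mean(log(p))

#' Aitchison distance between two compositions
#'
#' Euclidean distance of the centered log-ratio (clr) vectors — the
#' natural metric of simplex geometry. It is symmetric, zero iff the
#' compositions are equal, scale-invariant (multiplying a profile by a
#' positive scalar before closure changes nothing) and
#' perturbation-invariant.
#'
#' @param x,y `composition` objects over identical part sets.
#' @return nonnegative distance.
#' @export
aitchison_distance <- function(x, y) {
  stopifnot(inherits(x, "composition"), inherits(y, "composition"))
  if (!identical(x$parts, y$parts)) {
    dxy <- union(setdiff(x$parts, y$parts), setdiff(y$parts, x$parts))
    stop_fmt("aitchison_distance(): part sets differ (symmetric difference: %s)",
             paste(head(dxy, 5L), collapse = ", "))
  }
  sqrt(sum((clr(x$prop) - clr(y$prop))^2))
}

#' Complete-linkage clustering of composition profiles
#'
#' Agglomerative hierarchy over the pairwise Aitchison distance
#' matrix with complete linkage; deterministic given the input order.
#'
#' @param profiles list of `composition` objects (>= 2) over identical
#'   part sets, with unique ids.
#' @param linkage only `"complete"` is supported.
#' @return An `hclust` tree whose labels are the profile ids, with the
#'   distance matrix attached as attribute `dist`.
#' @export
cluster_profiles <- function(profiles, linkage = "complete") {
  linkage <- match.arg(linkage, "complete")
  if (length(profiles) < 2L)
    stop_fmt("cluster_profiles(): need >= 2 profiles")
  ids <- vapply(profiles, function(p) p$id %||% NA_character_, character(1))
  if (anyNA(ids)) ids <- paste0("p", seq_along(profiles))
  parts <- profiles[[1L]]$parts
  for (p in profiles) if (!identical(p$parts, parts))
    stop_fmt("cluster_profiles(): profiles have differing part sets")
  m <- t(vapply(profiles, function(p) clr(p$prop), numeric(length(parts))))
  rownames(m) <- ids
  d <- dist(m)   # Euclidean on clr = Aitchison
  tree <- hclust(d, method = "complete")
  attr(tree, "dist") <- d
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate dendrogram leaves with ontology classes
#'
#' Prefixes every leaf label with the topmost ontology class (the
#' first component of the class path) and flags classes with <= 3
#' members as small (the convention of leaving small classes uncolored
#' in published trees).
#'
#' @param tree `hclust` from [cluster_profiles()].
#' @param ontology data.table/data.frame `library_id`, `class_path`
#'   (slash-separated, topmost class first) covering every leaf.
#' @return list: `tree` (labels prefixed `class|library`), `leaves`
#'   (data.table `library_id`, `top_class`, `small_class`).
#' @export
annotate_leaves <- function(tree, ontology) {
  ont <- as.data.table(ontology)
  if (!nrow(ont)) stop_fmt("annotate_leaves(): empty ontology table")
  stopifnot(all(c("library_id", "class_path") %in% names(ont)))
  missing <- setdiff(tree$labels, ont$library_id)
  if (length(missing))
    stop_fmt("annotate_leaves(): leaf %s has no ontology entry", missing[1L])
  ont <- ont[match(tree$labels, library_id)]
  ont[, top_class := vapply(strsplit(class_path, "/", fixed = TRUE),
                            `[`, character(1), 1L)]
  ont[, small_class := .N <= 3L, by = top_class]
  out <- tree
  out$labels <- paste(ont$top_class, tree$labels, sep = "|")
  list(tree = out, leaves = ont[, .(library_id, top_class, small_class)])
}

#' Per-library mitochondrial locus-level composition profiles
#'
#' Pools sense + antisense TPM of within-boundary tags per
#' mitochondrial locus and library; one composition part per
#' mitochondrial locus with at least one DpnII site observed in the
#' annotation.
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()].
#' @param models a [gene_model_set()].
#' @param pseudocount pseudocount for [to_composition()].
#' @return named list of `composition` objects, one per library, plus
#'   attribute `matrix` (locus x library TPM).
#' @export
mito_profile <- function(atlas, annotation, models, pseudocount = 1) {
  mloci <- models$loci[mitochondrial == TRUE, locus_id]
  if (!length(mloci)) stop_fmt("mito_profile(): no mitochondrial loci in the models")
  dt <- .pair_tpm(atlas, annotation)[locus_id %chin% mloci]
  parts <- sort(intersect(mloci, unique(annotation$locus_id)))
  if (!length(parts))
    stop_fmt("mito_profile(): no annotated tags in mitochondrial loci")
  libs <- atlas$libraries$library_id
  m <- matrix(0, length(parts), length(libs), dimnames = list(parts, libs))
  agg <- dt[, .(tpm = sum(tpm)), by = .(locus_id, library_id)]
  if (nrow(agg))
    m[cbind(match(agg$locus_id, parts), match(agg$library_id, libs))] <- agg$tpm
  profs <- lapply(libs, function(l)
    to_composition(setNames(m[, l], parts), pseudocount = pseudocount, id = l))
  names(profs) <- libs
  attr(profs, "matrix") <- m
  profs
}

#' Tag-level composition profiles of an atlas
#'
#' One composition per library over a common tag universe (typically
#' the filtered, uniquely-mapping tag set), zeros handled by the
#' pseudocount.
#'
#' @param atlas a `tag_atlas`.
#' @param tags tag universe (default: all atlas tags).
#' @param pseudocount pseudocount for [to_composition()].
#' @return named list of `composition` objects.
#' @export
atlas_profiles <- function(atlas, tags = NULL, pseudocount = 1) {
  m <- atlas_matrix(if (is.null(tags)) atlas else subset_atlas(atlas, tags))
  lapply(setNames(colnames(m), colnames(m)), function(l)
    to_composition(setNames(m[, l], rownames(m)), pseudocount = pseudocount,
                   id = l))
}

#' Write an hclust tree as Newick with branch heights
#'
#' @param tree `hclust`.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}
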