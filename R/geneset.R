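#' Construct a gene set structure
#'
#' A gene set structure holds the two mappings used by gene set-based tPOD
#' derivation: a probeset-to-gene map and a gene-to-gene-set map. Probesets
#' mapping to more than one gene are representable and flagged; they are
#' excluded later, at BMD-to-gene aggregation. Gene sets may overlap unless
#' the structure is declared non-overlapping (e.g., co-expression modules).
#'
#' @param probe_to_gene data frame with character columns `probeset_id` and
#'   `gene_id` (one row per mapping; a probeset may appear in several rows).
#' @param set_members named list; element names are gene-set ids, elements are
#'   character vectors of member gene ids. Duplicated members are dropped;
#'   empty sets are removed.
#' @param set_names optional named character vector of display names keyed by
#'   set id; defaults to the ids themselves.
#' @return An object of class `gene_set_structure` with elements
#'   `probe_to_gene`, `set_members`, `set_names`, and `multi_gene_probesets`
#'   (ids of probesets mapped to more than one gene).
#' @export
gene_set_structure <- function(probe_to_gene, set_members, set_names = NULL) {
  stopifnot(is.data.frame(probe_to_gene),
            all(c("probeset_id", "gene_id") %in% names(probe_to_gene)))
  probe_to_gene <- data.frame(
    probeset_id = as.character(probe_to_gene$probeset_id),
    gene_id = as.character(probe_to_gene$gene_id),
    stringsAsFactors = FALSE)
  probe_to_gene <- unique(probe_to_gene)
  if (!is.list(set_members) || is.null(names(set_members)))
    stop("`set_members` must be a named list of gene id vectors")
  set_members <- lapply(set_members, function(g) unique(as.character(g)))
  set_members <- set_members[lengths(set_members) > 0]
  if (is.null(set_names)) {
    set_names <- stats::setNames(names(set_members), names(set_members))
  } else {
    set_names <- set_names[names(set_members)]
    set_names[is.na(set_names)] <- names(set_members)[is.na(set_names)]
    names(set_names) <- names(set_members)
  }
  ngene <- tapply(probe_to_gene$gene_id, probe_to_gene$probeset_id,
                  function(g) length(unique(g)))
  multi <- names(ngene)[ngene > 1]
  structure(list(probe_to_gene = probe_to_gene,
                 set_members = set_members,
                 set_names = set_names,
                 multi_gene_probesets = multi),
            class = "gene_set_structure")
}

#' @export
print.gene_set_structure <- function(x, ...) {
  cat("Gene set structure\n")
  cat(sprintf("  %d gene sets (median size %s genes)\n",
              length(x$set_members),
              format(stats::median(lengths(x$set_members)))))
  cat(sprintf("  probe map: %d probesets -> %d genes (%d multi-gene probesets)\n",
              length(unique(x$probe_to_gene$probeset_id)),
              length(unique(x$probe_to_gene$gene_id)),
              length(x$multi_gene_probesets)))
  invisible(x)
}

#' Read a gene set structure from annotation TSVs
#'
#' Reads the two tab-delimited annotation files of the "defined category"
#' dialect: a probe map with columns (probeset_id, gene_id) and a category
#' map with columns (set_id, set_name, gene_id). Both files carry a header
#' row. Duplicate (set_id, gene_id) pairs are deduplicated. Genes appearing
#' in the category map but absent from the probe map are kept; they count
#' toward set sizes only where a platform exposes them.
#'
#' @param probe_map_path path to the probeset-to-gene TSV.
#' @param category_map_path path to the gene-set membership TSV.
#' @return a [gene_set_structure()].
#' @export
read_gene_set_structure <- function(probe_map_path, category_map_path) {
  for (p in c(probe_map_path, category_map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  pm <- utils::read.delim(probe_map_path, colClasses = "character")
  if (nrow(pm) == 0) stop("format error: empty probe map file")
  if (ncol(pm) < 2) stop("format error: probe map needs 2 columns")
  names(pm)[1:2] <- c("probeset_id", "gene_id")
  cm <- utils::read.delim(category_map_path, colClasses = "character")
  if (nrow(cm) == 0) stop("format error: empty category map file")
  if (ncol(cm) < 3)
    stop("format error: category map needs 3 columns (set id, name, gene)")
  names(cm)[1:3] <- c("set_id", "set_name", "gene_id")
  cm <- cm[!duplicated(cm[c("set_id", "gene_id")]), ]
  members <- split(cm$gene_id, cm$set_id)
  nm <- vapply(split(cm$set_name, cm$set_id), `[[`, character(1), 1L)
  gene_set_structure(pm[c("probeset_id", "gene_id")], members, nm)
}

#' Write a gene set structure to annotation TSVs
#'
#' Emits the same two-file dialect read by [read_gene_set_structure()].
#'
#' @param structure a `gene_set_structure`.
#' @param probe_map_path,category_map_path output file paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_gene_set_structure <- function(structure, probe_map_path,
                                     category_map_path) {
  utils::write.table(structure$probe_to_gene, probe_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- data.frame(
    set_id = rep(names(structure$set_members),
                 lengths(structure$set_members)),
    set_name = rep(unname(structure$set_names[names(structure$set_members)]),
                   lengths(structure$set_members)),
    gene_id = unlist(structure$set_members, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(cm, category_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(probe_map_path, category_map_path))
}

#' Platform-restricted set sizes
#'
#' Set sizes are reported against a platform: the size of a set is the number
#' of its member genes that the platform's probe map exposes.
#'
#' @param structure a `gene_set_structure`.
#' @param platform_probesets character vector of probeset ids on the platform.
#' @return named integer vector of platform-restricted set sizes (sets with
#'   zero platform members are included with size 0).
#' @export
platform_set_sizes <- function(structure, platform_probesets) {
  pm <- structure$probe_to_gene
  genes <- unique(pm$gene_id[pm$probeset_id %in% platform_probesets])
  vapply(structure$set_members,
         function(g) sum(g %in% genes), integer(1))
}

#' Mapping statistics of a structure against a platform
#'
#' Quantifies how much of a platform a gene set structure can use: probesets
#' whose mapped gene belongs to no set (or that map to no gene at all) are
#' unmapped and cannot contribute to gene set-based tPOD derivation.
#'
#' @param structure a `gene_set_structure`.
#' @param platform_probesets non-empty character vector of probeset ids.
#' @return list with `n_sets` (sets with at least one platform gene),
#'   `median_set_size` (median platform-restricted size of those sets),
#'   `n_genes_covered` (platform genes occurring in at least one set) and
#'   `pct_probesets_unmapped` (percent of platform probesets not usable).
#' @export
structure_stats <- function(structure, platform_probesets) {
  platform_probesets <- as.character(platform_probesets)
  if (length(platform_probesets) == 0)
    stop("platform_probesets must be non-empty")
  pm <- structure$probe_to_gene
  set_genes <- unique(unlist(structure$set_members, use.names = FALSE))
  pm_on <- pm[pm$probeset_id %in% platform_probesets, , drop = FALSE]
  mapped_probesets <- unique(pm_on$probeset_id[pm_on$gene_id %in% set_genes])
  sizes <- platform_set_sizes(structure, platform_probesets)
  sizes <- sizes[sizes > 0]
  platform_genes <- unique(pm_on$gene_id)
  list(
    n_sets = length(sizes),
    median_set_size = if (length(sizes)) stats::median(sizes) else NA_real_,
    n_genes_covered = sum(platform_genes %in% set_genes),
    pct_probesets_unmapped =
      100 * (1 - length(mapped_probesets) / length(platform_probesets)))
}

#' Gene overlap counts across several structures
#'
#' Computes, over the union of genes referenced by the set members of each
#' structure, the total number of distinct genes, the number common to all
#' structures, and the number unique to a single structure.
#'
#' @param structures a list of `gene_set_structure` objects.
#' @return list with `n_union`, `n_common_all`, `n_unique_single`.
#' @export
structure_overlap_counts <- function(structures) {
  gene_lists <- lapply(structures, function(s)
    unique(unlist(s$set_members, use.names = FALSE)))
  all_genes <- unique(unlist(gene_lists, use.names = FALSE))
  counts <- rowSums(vapply(gene_lists, function(g) all_genes %in% g,
                           logical(length(all_genes))))
  list(n_union = length(all_genes),
       n_common_all = sum(counts == length(gene_lists)),
       n_unique_single = sum(counts == 1))
}
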