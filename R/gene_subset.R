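#' Construct a gene subset with provenance
#'
#' A `gene_subset` is an ordered set of gene identifiers together with a
#' record of how it was produced: the method name, its parameters, and
#' optionally the upstream subset it was drawn from (e.g. the stage-1
#' candidate set behind a stage-2 selection).
#'
#' @param gene_ids Character vector of unique gene identifiers (may be
#'   empty).
#' @param method Provenance string naming the producing method.
#' @param params Named list of method parameters.
#' @param parent Optional upstream `gene_subset`; `gene_ids` must be a
#'   subset of the parent's.
#' @return An object of class `gene_subset`.
#' @export
gene_subset <- function(gene_ids, method = "manual", params = list(),
                        parent = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) abort("duplicate gene_ids in subset")
  if (!is.null(parent)) {
    stopifnot(inherits(parent, "gene_subset"))
    extra <- setdiff(gene_ids, parent$gene_ids)
    if (length(extra) > 0) {
      abort(sprintf("gene_ids not in parent subset: %s",
                    paste(utils::head(extra, 5), collapse = ", ")))
    }
  }
  structure(list(gene_ids = gene_ids, method = method, params = params,
                 parent = parent),
            class = "gene_subset")
}

# Accept a gene_subset, ranked_genes table, or character vector.
as_gene_ids <- function(x) {
  if (inherits(x, "gene_subset")) return(x$gene_ids)
  if (inherits(x, "ranked_genes") || (is.data.frame(x) && "gene_id" %in% names(x))) {
    return(as.character(x$gene_id))
  }
  as.character(x)
}

#' @export
length.gene_subset <- function(x) length(x$gene_ids)

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("<gene_subset> %d gene(s) selected by '%s'\n",
              length(x$gene_ids), x$method))
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params),
                           vapply(x$params, function(v) paste(format(v), collapse = ","), ""),
                           sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$parent)) {
    cat(sprintf("  parent: %d gene(s) from '%s'\n",
                length(x$parent$gene_ids), x$parent$method))
  }
  if (length(x$gene_ids) > 0) {
    cat("  genes:", paste(utils::head(x$gene_ids, 10), collapse = ", "),
        if (length(x$gene_ids) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @method tidy gene_subset
#' @export
tidy.gene_subset <- function(x, ...) {
  tibble(rank = seq_along(x$gene_ids), gene_id = x$gene_ids)
}

#' Write a gene subset to TSV with a JSON provenance side-car
#'
#' Writes `rank`/`gene_id` rows to `path` and the method, parameters, and
#' parent chain to `<path>.json`.
#'
#' @param x A `gene_subset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_subset <- function(x, path) {
  stopifnot(inherits(x, "gene_subset"))
  readr::write_tsv(tidy(x), path, progress = FALSE)
  prov <- list(method = x$method, params = x$params,
               n_genes = length(x$gene_ids),
               parent = if (!is.null(x$parent)) {
                 list(method = x$parent$method,
                      n_genes = length(x$parent$gene_ids))
               })
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}
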