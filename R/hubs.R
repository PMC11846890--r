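#' Weighted senescence gene hub
#'
#' A hub is one Louvain community of co-positive age-dynamic genes. Each gene
#' carries an importance value: its number of edges to other genes within the
#' hub. All hubs from one cell type together form that cell type's signature.
#'
#' @param hub_id Unique identifier string.
#' @param genes Named integer vector (or named list) mapping gene symbol to
#'   importance (within-hub degree, >= 1).
#' @param species,tissue,cell_type Provenance strings.
#' @param metadata Optional named list of free-form annotations.
#' @param min_size Minimum number of genes (5 for hubs emitted by discovery;
#'   lower values are allowed for hand-built composite panels).
#' @return An object of class `senesig_hub`.
#' @export
#' @examples
#' hub("h1", c(Cdkn2a = 3, Cdkn1a = 2, Trp53 = 2, Ccl5 = 1, Ccl8 = 1),
#'   species = "mouse", tissue = "lung", cell_type = "fibroblast"
#' )
hub <- function(hub_id, genes, species = "unspecified", tissue = "unspecified",
                cell_type = "unspecified", metadata = list(), min_size = 1L) {
  genes <- unlist(genes)
  if (is.null(names(genes)) || any(names(genes) == "")) {
    abort("hub genes must be a named vector of importances",
      class = "senesig_schema_error"
    )
  }
  if (anyDuplicated(names(genes))) {
    abort("hub gene symbols must be unique", class = "senesig_schema_error")
  }
  if (any(genes < 1)) {
    abort("hub importances must be >= 1", class = "senesig_schema_error")
  }
  if (length(genes) < min_size) {
    abort(sprintf(
      "hub '%s' has %d genes; at least %d required",
      hub_id, length(genes), min_size
    ), class = "senesig_schema_error")
  }
  structure(
    list(
      hub_id = as.character(hub_id), species = species, tissue = tissue,
      cell_type = cell_type,
      genes = setNames(as.numeric(genes), names(genes)),
      metadata = metadata
    ),
    class = "senesig_hub"
  )
}

#' @export
print.senesig_hub <- function(x, ...) {
  cat(sprintf(
    "<hub %s> %s/%s/%s — %d genes (top: %s)\n",
    x$hub_id, x$species, x$tissue, x$cell_type, length(x$genes),
    paste(head(names(sort(x$genes, decreasing = TRUE)), 5), collapse = ", ")
  ))
  invisible(x)
}

#' @export
length.senesig_hub <- function(x) length(x$genes)

#' Collection of hubs with an optional background gene universe
#'
#' @param hubs List of [hub()] objects.
#' @param background_genes Optional character vector: the dataset-wide
#'   expressed-gene universe used as the background for overlap and
#'   overrepresentation tests. When present it must contain every hub gene.
#' @return An object of class `senesig_hub_collection`.
#' @export
hub_collection <- function(hubs, background_genes = NULL) {
  if (inherits(hubs, "senesig_hub")) hubs <- list(hubs)
  stopifnot(all(vapply(hubs, inherits, logical(1), "senesig_hub")))
  ids <- vapply(hubs, `[[`, character(1), "hub_id")
  if (anyDuplicated(ids)) {
    abort("hub_ids must be unique within a collection",
      class = "senesig_schema_error"
    )
  }
  if (!is.null(background_genes)) {
    all_genes <- unique(unlist(lapply(hubs, function(h) names(h$genes))))
    outside <- setdiff(all_genes, background_genes)
    if (length(outside)) {
      abort(sprintf(
        "%d hub gene(s) absent from background_genes (e.g. %s)",
        length(outside), paste(head(outside, 3), collapse = ", ")
      ), class = "senesig_schema_error")
    }
  }
  structure(
    list(hubs = setNames(hubs, ids), background_genes = background_genes),
    class = "senesig_hub_collection"
  )
}

#' @export
length.senesig_hub_collection <- function(x) length(x$hubs)

#' @export
print.senesig_hub_collection <- function(x, ...) {
  cat(sprintf(
    "<hub_collection> %d hubs, background: %s genes\n", length(x$hubs),
    if (is.null(x$background_genes)) "none" else length(x$background_genes)
  ))
  for (h in x$hubs) print(h)
  invisible(x)
}

#' Write a hub collection to JSON
#'
#' Schema: `{"schema_version": 1, "background_genes": [...]|null,
#' "hubs": [{"hub_id", "species", "tissue", "cell_type",
#' "genes": {symbol: importance}, "metadata": {}}]}`.
#'
#' @param collection A [hub_collection()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_hubs <- function(collection, path) {
  stopifnot(inherits(collection, "senesig_hub_collection"))
  obj <- list(
    schema_version = 1L,
    background_genes = collection$background_genes,
    hubs = lapply(unname(collection$hubs), function(h) {
      list(
        hub_id = h$hub_id, species = h$species, tissue = h$tissue,
        cell_type = h$cell_type, genes = as.list(h$genes),
        metadata = h$metadata
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a hub collection from JSON, optionally filtered
#'
#' @param path JSON file written by [write_hubs()] (schema above).
#' @param species,tissue,cell_type Optional filters; only hubs matching all
#'   supplied values are returned.
#' @return A [hub_collection()].
#' @export
load_hubs <- function(path, species = NULL, tissue = NULL, cell_type = NULL) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$hubs)) {
    abort(sprintf("%s: missing required key 'hubs'", path),
      class = "senesig_schema_error"
    )
  }
  hubs <- lapply(obj$hubs, function(h) {
    for (key in c("hub_id", "genes")) {
      if (is.null(h[[key]])) {
        abort(sprintf("%s: hub entry missing required key '%s'", path, key),
          class = "senesig_schema_error"
        )
      }
    }
    hub(
      h$hub_id,
      setNames(vapply(h$genes, as.numeric, numeric(1)), names(h$genes)),
      species = h$species %||% "unspecified",
      tissue = h$tissue %||% "unspecified",
      cell_type = h$cell_type %||% "unspecified",
      metadata = h$metadata %||% list()
    )
  })
  keep <- vapply(hubs, function(h) {
    (is.null(species) || h$species %in% species) &&
      (is.null(tissue) || h$tissue %in% tissue) &&
      (is.null(cell_type) || h$cell_type %in% cell_type)
  }, logical(1))
  bg <- if (is.null(obj$background_genes)) NULL else unlist(obj$background_genes)
  hub_collection(hubs[keep], background_genes = bg)
}

#' Tidy a hub collection into a gene-level tibble
#'
#' @param x A `senesig_hub_collection`.
#' @param ... Unused.
#' @return A tibble with one row per (hub, gene): `hub_id`, `species`,
#'   `tissue`, `cell_type`, `gene`, `importance`.
#' @export
tidy.senesig_hub_collection <- function(x, ...) {
  purrr::map_dfr(x$hubs, function(h) {
    tibble(
      hub_id = h$hub_id, species = h$species, tissue = h$tissue,
      cell_type = h$cell_type, gene = names(h$genes),
      importance = unname(h$genes)
    )
  })
}
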