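#' Read a gene-alias table
#'
#' @param path Two-column headered TSV with columns `alias` and `canonical`.
#' @return A named character vector mapping alias to canonical symbol.
#' @export
read_alias_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("alias", "canonical"), names(tab))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), class = "senesig_schema_error")
  }
  if (anyDuplicated(tab$alias)) {
    abort("alias table maps an alias to more than one canonical symbol",
      class = "senesig_schema_error"
    )
  }
  setNames(as.character(tab$canonical), as.character(tab$alias))
}

#' Harmonize gene symbols against a dataset's gene universe
#'
#' Symbols already present verbatim in `target_universe` are never rewritten
#' (exact match beats alias substitution). Symbols absent from the universe
#' are replaced by an alias that is present when one exists; otherwise they
#' are dropped with an informative message. For hubs, importances travel with
#' their gene; if two symbols of a hub collapse onto one universe symbol the
#' canonical entry is kept and a collision warning is issued. Comparison is
#' case-sensitive: alias tables are responsible for case harmonization.
#'
#' @param x A character vector of gene symbols, or a [hub()].
#' @param alias_map Named character vector from [read_alias_map()]
#'   (alias -> canonical), or `NULL` for drop-only filtering.
#' @param target_universe Character vector: the dataset's gene symbols.
#' @param quiet Suppress the dropped-gene message.
#' @return Same shape as `x`, restricted to the target universe.
#' @export
translate <- function(x, alias_map, target_universe, quiet = FALSE) {
  UseMethod("translate")
}

translate_symbols <- function(genes, alias_map, target_universe) {
  out <- as.character(genes)
  miss <- !(out %in% target_universe)
  if (any(miss) && length(alias_map)) {
    candidate <- unname(alias_map[out[miss]])
    ok <- !is.na(candidate) & candidate %in% target_universe
    out[miss][ok] <- candidate[ok]
  }
  out[!(out %in% target_universe)] <- NA_character_
  out
}

#' @export
translate.character <- function(x, alias_map, target_universe, quiet = FALSE) {
  mapped <- translate_symbols(x, alias_map, target_universe)
  dropped <- sum(is.na(mapped))
  if (dropped && !quiet) {
    inform(sprintf("translate: dropped %d gene(s) not mappable into the universe", dropped))
  }
  unique(mapped[!is.na(mapped)])
}

#' @export
translate.senesig_hub <- function(x, alias_map, target_universe, quiet = FALSE) {
  mapped <- translate_symbols(names(x$genes), alias_map, target_universe)
  keep <- !is.na(mapped)
  dropped <- sum(!keep)
  if (dropped && !quiet) {
    inform(sprintf(
      "translate: hub '%s' lost %d gene(s) not mappable into the universe",
      x$hub_id, dropped
    ))
  }
  genes <- x$genes[keep]
  names(genes) <- mapped[keep]
  if (anyDuplicated(names(genes))) {
    dup <- unique(names(genes)[duplicated(names(genes))])
    warn(sprintf(
      "translate: hub '%s' has alias collisions on %s; keeping the canonical entry",
      x$hub_id, paste(dup, collapse = ", ")
    ))
    # the canonical entry is the one whose symbol was already in the universe
    orig_in_universe <- names(x$genes)[keep] %in% target_universe
    ord <- order(!orig_in_universe) # canonical (exact-match) entries first
    genes <- genes[ord][!duplicated(names(genes)[ord])]
  }
  if (!length(genes)) {
    abort(sprintf("hub '%s': no gene present in the target universe", x$hub_id),
      class = "senesig_data_error"
    )
  }
  hub(x$hub_id, genes,
    species = x$species, tissue = x$tissue,
    cell_type = x$cell_type, metadata = x$metadata
  )
}

#' @export
translate.senesig_hub_collection <- function(x, alias_map, target_universe,
                                             quiet = FALSE) {
  hub_collection(
    lapply(unname(x$hubs), translate, alias_map = alias_map,
           target_universe = target_universe, quiet = quiet),
    background_genes = if (is.null(x$background_genes)) {
      NULL
    } else {
      translate.character(x$background_genes, alias_map, target_universe,
        quiet = quiet
      )
    }
  )
}
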