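# Residue-group atom selection.

#' Define a residue group on one chain
#'
#' A `group_spec` names a set of author-numbered residues on a chain, the
#' unit in which gate metrics, alignment selections and binding sites are
#' declared.
#'
#' @param chain_id Single chain identifier.
#' @param residues Integer vector of residue numbers (non-empty).
#' @param heavy_only Drop hydrogens/deuteriums on selection (default `TRUE`).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(chain_id, residues, heavy_only = TRUE) {
  check_that(is.character(chain_id) && length(chain_id) == 1L && nzchar(chain_id),
             "chain_id must be a single non-empty string")
  residues <- as.integer(residues)
  check_that(length(residues) >= 1L && !anyNA(residues),
             "residues must be a non-empty integer vector")
  structure(list(chain_id = chain_id, residues = sort(unique(residues)),
                 heavy_only = isTRUE(heavy_only)),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("group_spec: chain %s, %d residue(s) [%s]%s\n",
              x$chain_id, length(x$residues),
              paste(range(x$residues), collapse = ".."),
              if (x$heavy_only) ", heavy atoms only" else ""))
  invisible(x)
}

#' Select the atoms of a residue group
#'
#' Returns all atoms of the listed residues on the spec's chain, in
#' deterministic order (residue number, then file order). Every listed
#' residue must exist in the model: a group selecting nothing is a
#' configuration error, never an empty result.
#'
#' @param model A `StructureModel`.
#' @param spec A [group_spec()] or a list of them (concatenated in order).
#' @return Atom `data.frame` subset (same columns as `model$atoms`).
#' @export
select_atoms <- function(model, spec) {
  if (inherits(spec, "group_spec")) spec <- list(spec)
  out <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    check_that(inherits(s, "group_spec"), "spec must be group_spec object(s)")
    a <- model$atoms
    on_chain <- a$chain_id == s$chain_id
    present <- unique(a$res_seq[on_chain])
    missing <- setdiff(s$residues, present)
    check_that(length(missing) == 0L,
               "model '%s': chain %s is missing residue(s) %s",
               model$model_id, s$chain_id, paste(missing, collapse = ", "))
    rows <- which(on_chain & a$res_seq %in% s$residues)
    if (s$heavy_only) rows <- rows[!a$is_hydrogen[rows]]
    # stable order: residue number first, then file order inside a residue
    rows <- rows[order(a$res_seq[rows], rows)]
    out[[i]] <- a[rows, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
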