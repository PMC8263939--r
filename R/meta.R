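#' @title Meta-integration of per-dataset DEG sets
#' @description Combines per-dataset, per-comparison DEG calls by
#'   direction-consistent intersection within each comparison class
#'   (MvsN, PvsN, MvsP), filters the union against validation datasets,
#'   selects the core gene set, and builds direction/concordance tables.
#' @name meta_integration
NULL

#' Direction-consistent intersection of DEG sets
#'
#' A gene survives iff it is present in every input set with the same
#' direction everywhere; genes with discordant directions are excluded.
#'
#' @param deg_sets Non-empty list of data.frames `(gene, direction)`.
#' @return data.frame `(gene, direction)`.
#' @export
intersect_class <- function(deg_sets) {
  if (!length(deg_sets)) stop_io("intersect_class needs >= 1 DEG set")
  out <- unique(deg_sets[[1L]][c("gene", "direction")])
  for (s in deg_sets[-1L]) {
    s <- unique(s[c("gene", "direction")])
    out <- merge(out, s, by = c("gene", "direction"))
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter the union of class intersections against validation datasets
#'
#' A gene from the test-dataset consensus is kept iff, in every validation
#' analysis of the matching comparison class in which it is measured, it
#' shows `|logFC| >= presence_cut` with the consensus direction.  Genes not
#' measured in a validation dataset are not penalized.  Under
#' `allow_one_discordant = TRUE` a single discordant validation analysis is
#' tolerated.
#'
#' @param class_intersections Named list (`MvsN`, `PvsN`, `MvsP`) of
#'   consensus data.frames `(gene, direction)` from [intersect_class()].
#' @param validation_results Named list: for each class, a list of
#'   `de_result` objects from validation datasets (may be empty).
#' @param presence_cut Minimum |logFC| for a validation cell to count
#'   (default 0.2, the reporting cutoff).
#' @param allow_one_discordant Tolerate one discordant validation analysis?
#' @return data.frame `(gene, class, direction)` of final DEGs.
#' @export
final_deg_set <- function(class_intersections, validation_results,
                          presence_cut = 0.2, allow_one_discordant = FALSE) {
  rows <- list()
  for (cls in names(class_intersections)) {
    cons <- class_intersections[[cls]]
    if (!nrow(cons)) next
    vres <- validation_results[[cls]]
    keep <- rep(TRUE, nrow(cons))
    discord <- integer(nrow(cons))
    for (vr in vres) {
      idx <- match(cons$gene, vr$gene)
      measured <- !is.na(idx) & abs(vr$logFC[idx]) >= presence_cut
      vdir <- ifelse(vr$logFC[idx] > 0, "Up", "Down")
      bad <- measured & vdir != cons$direction
      discord <- discord + as.integer(bad)
    }
    keep <- if (allow_one_discordant) discord <= 1L else discord == 0L
    if (any(keep))
      rows[[cls]] <- data.frame(gene = cons$gene[keep], class = cls,
                                direction = cons$direction[keep],
                                stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(), class = character(),
                         direction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the core gene set
#'
#' Default rule: the metastatic-versus-primary (MvsP) consensus genes that
#' survived validation.  A user-supplied gene list overrides the rule and
#' is used verbatim.
#'
#' @param class_intersections Named list of consensus sets (needs `MvsP`).
#' @param validated_final Output of [final_deg_set()].
#' @param user_core Optional character vector of core genes.
#' @return Character vector of core genes (non-empty, or an error).
#' @export
select_core_genes <- function(class_intersections, validated_final,
                              user_core = NULL) {
  if (!is.null(user_core)) {
    core <- unique(as.character(user_core))
  } else {
    mvp <- class_intersections[["MvsP"]]
    if (is.null(mvp) || !nrow(mvp))
      stop_io("MvsP intersection is empty and no core list was supplied")
    core <- intersect(mvp$gene,
                      validated_final$gene[validated_final$class == "MvsP"])
  }
  if (!length(core)) stop_io("core gene set is empty; Dj is undefined")
  core
}

#' Direction table across analyses
#'
#' One row per gene, one column per analysis; cells are `Up`/`Down` by the
#' sign of logFC when `|logFC| >= report_cut`, otherwise blank (`""`).
#' Genes absent from a dataset also get a blank cell.
#'
#' @param results Named list of `de_result` objects (names label columns).
#' @param genes Genes to report (rows).
#' @param report_cut Reporting cutoff on |logFC| (default 0.2; a value of
#'   exactly 0.2 is reported).
#' @return Character matrix genes x analyses.
#' @export
direction_table <- function(results, genes, report_cut = 0.2) {
  tab <- matrix("", nrow = length(genes), ncol = length(results),
                dimnames = list(genes, names(results)))
  for (k in seq_along(results)) {
    vr <- results[[k]]
    idx <- match(genes, vr$gene)
    lfc <- vr$logFC[idx]
    cell <- ifelse(is.na(lfc) | abs(lfc) < report_cut, "",
                   ifelse(lfc > 0, "Up", "Down"))
    tab[, k] <- cell
  }
  tab
}

#' Classify the concordance of a direction-table row
#'
#' Blanks are ignored.  `uniform` when all non-blank cells agree;
#' `one_discordant` when exactly one cell disagrees with the majority;
#' `heterogeneous` otherwise; `undefined` for an all-blank row.
#'
#' @param row Character vector of `Up`/`Down`/`""` cells.
#' @return One of `"uniform"`, `"one_discordant"`, `"heterogeneous"`,
#'   `"undefined"`.
#' @export
classify_concordance <- function(row) {
  cells <- row[nzchar(row)]
  if (!length(cells)) return("undefined")
  n_up <- sum(cells == "Up"); n_down <- sum(cells == "Down")
  minority <- min(n_up, n_down)
  if (minority == 0L) "uniform"
  else if (minority == 1L) "one_discordant"
  else "heterogeneous"
}
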