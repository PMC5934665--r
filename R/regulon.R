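#' Classify promoters into regulon groups by binding and expression
#'
#' Implements the central inference: a promoter joins Group I (Fnr1-only),
#' Group II (Fnr3-only) or Group III (bound by both) when it carries a
#' significant peak for the corresponding factor(s) at `peak_alpha` and
#' shows the matching deletion-dependent expression change.
#'
#' Binding: the best peak p-value per factor is compared with the strict
#' membership threshold (`peak_alpha`, default 1e-5). A promoter counts as
#' *exclusively* bound by one factor only when the other factor shows no
#' peak even at the relaxed screening threshold (`ambiguous_alpha`,
#' default 1e-4); a sub-threshold other-factor peak
#' (`peak_alpha <= p < ambiguous_alpha`) makes the call ambiguous and the
#' promoter is reported with group `none` rather than silently assigned an
#' exclusive group. This also makes the assignment monotone in
#' `peak_alpha`: tightening it can drop a promoter to `none` but never
#' moves it between groups.
#'
#' Expression evidence, from the seven-comparison DE table:
#' * activated - significantly up in WTCvWTS and significantly down in
#'   WTSvDxS for every bound factor x (for Group I the additional Fnr3
#'   dependence, down in WTSvD3S, is recorded as `fnr3_dependent` but does
#'   not define the group);
#' * repressed - significantly down in WTCvWTS and up in WTSvDxS for every
#'   bound factor.
#'
#' Promoters bound without expression evidence get group `none` with
#' reason `bound_no_de`. A repressed Group III call (never observed in the
#' study) is kept but flagged `deviation`.
#'
#' @param links_fnr1,links_fnr3 promoter-peak link tables from
#'   [peak_at_promoter()] for the two factors.
#' @param de DE table from [run_comparisons()].
#' @param peak_alpha strict peak p-value threshold for group membership.
#' @param ambiguous_alpha relaxed threshold below which an other-factor
#'   peak blocks an exclusive call.
#' @return data.frame of class `regulon_assignments`: gene, bound_by,
#'   group, mode, p_fnr1, p_fnr3, ambiguous, fnr3_dependent, reason.
#' @export
classify_regulons <- function(links_fnr1, links_fnr3, de,
                              peak_alpha = 1e-5, ambiguous_alpha = 1e-4) {
  stopifnot(peak_alpha <= ambiguous_alpha)
  best_p <- function(links, gene) {
    if (nrow(links) == 0L) return(Inf)
    p <- links$peak_p[links$gene_id == gene]
    if (length(p)) min(p) else Inf
  }
  genes <- sort(unique(c(links_fnr1$gene_id, links_fnr3$gene_id)))
  de_flag <- function(gene, cmp, dir) {
    row <- de[de$gene == gene & de$comparison == cmp, , drop = FALSE]
    nrow(row) == 1L && row$significant && row$direction == dir
  }

  out <- lapply(genes, function(g) {
    p1 <- best_p(links_fnr1, g)
    p3 <- best_p(links_fnr3, g)
    s1 <- p1 < peak_alpha; s3 <- p3 < peak_alpha
    l1 <- p1 < ambiguous_alpha; l3 <- p3 < ambiguous_alpha
    ambiguous <- (l1 && !s1 && s3) || (l3 && !s3 && s1)

    bound <- character(0)
    candidate <- "none"
    if (s1 && s3) { bound <- c("Fnr1", "Fnr3"); candidate <- "III" }
    else if (s1 && !l3) { bound <- "Fnr1"; candidate <- "I" }
    else if (s3 && !l1) { bound <- "Fnr3"; candidate <- "II" }
    else if (s1 || s3) bound <- c("Fnr1", "Fnr3")[c(s1, s3)]

    in_de <- g %in% de$gene
    mode <- "none"; group <- "none"; reason <- ""
    fnr3_dep <- NA
    if (!in_de) {
      reason <- "missing_from_de"
      if (candidate != "none") warning("gene ", g, " absent from DE table")
    } else if (candidate != "none") {
      down_in_del <- vapply(bound, function(f) {
        de_flag(g, if (f == "Fnr1") "WTSvD1S" else "WTSvD3S", "down")
      }, logical(1))
      up_in_del <- vapply(bound, function(f) {
        de_flag(g, if (f == "Fnr1") "WTSvD1S" else "WTSvD3S", "up")
      }, logical(1))
      if (de_flag(g, "WTCvWTS", "up") && all(down_in_del)) {
        mode <- "activated"; group <- candidate
      } else if (de_flag(g, "WTCvWTS", "down") && all(up_in_del)) {
        mode <- "repressed"; group <- candidate
        if (candidate == "III") reason <- "deviation"
      } else {
        reason <- "bound_no_de"
      }
      if (group == "I") fnr3_dep <- de_flag(g, "WTSvD3S", "down")
    } else {
      reason <- if (ambiguous) "ambiguous_binding" else "subthreshold_binding"
    }

    data.frame(gene = g,
               bound_by = paste(bound, collapse = ","),
               group = group, mode = mode,
               p_fnr1 = p1, p_fnr3 = p3,
               ambiguous = ambiguous,
               fnr3_dependent = fnr3_dep,
               reason = reason,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), bound_by = character(),
               group = character(), mode = character(),
               p_fnr1 = numeric(), p_fnr3 = numeric(),
               ambiguous = logical(), fnr3_dependent = logical(),
               reason = character(), stringsAsFactors = FALSE)
  class(res) <- c("regulon_assignments", "data.frame")
  res
}

#' Summarize regulon assignments
#'
#' Tabulates group sizes, the activated/repressed breakdown and the
#' per-factor totals, which satisfy the partition identities
#' Fnr1 total = Group I + Group III and Fnr3 total = Group II + Group III.
#'
#' @param assignments a [classify_regulons()] table.
#' @return list: `groups` (named counts I/II/III/none), `modes` (counts
#'   per group x activated/repressed), `fnr1_total`, `fnr3_total`,
#'   `n_ambiguous`, `n_bound_no_de`.
#' @export
summarize_regulons <- function(assignments) {
  g <- factor(assignments$group, levels = c("I", "II", "III", "none"))
  groups <- as.list(table(g))
  modes <- table(factor(assignments$group, levels = c("I", "II", "III")),
                 factor(assignments$mode, levels = c("activated", "repressed")))
  list(
    groups = setNames(as.integer(groups), names(groups)),
    modes = as.data.frame.matrix(modes),
    fnr1_total = as.integer(groups$I + groups$III),
    fnr3_total = as.integer(groups$II + groups$III),
    n_ambiguous = sum(assignments$ambiguous),
    n_bound_no_de = sum(assignments$reason == "bound_no_de")
  )
}
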