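write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build scan parameters from a configuration list
#'
#' Accepts the (YAML-derived) configuration of a run: any of the
#' [scan_params()] fields plus `min_similarity` and `max_gap`. Unknown keys
#' are an error so typos do not silently fall back to defaults.
#'
#' @param config Named list (e.g. from `yaml::read_yaml`), or `NULL`.
#' @return List with `params` ([scan_params()]), `min_similarity`,
#'   `max_gap`.
#' @export
resolve_config <- function(config = NULL) {
  defaults <- list(min_similarity = 70, max_gap = 30L)
  sp_names <- names(formals(scan_params))
  if (!is.null(config)) {
    unknown <- setdiff(names(config), c(sp_names, names(defaults)))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  sp_args <- if (is.null(config)) list()
             else config[intersect(names(config), sp_names)]
  for (k in names(defaults))
    if (!is.null(config[[k]])) defaults[[k]] <- config[[k]]
  c(list(params = do.call(scan_params, sp_args)), defaults)
}

#' Run the full scan/classify pipeline on a FASTA file
#'
#' Produces the architecture report, the motif report and the subfamily
#' calls, and writes them as TSV into `out_dir` together with the effective
#' configuration. When a labelled panel is supplied, `gli/glis/nkl-like`
#' calls are refined by placement and a neighbor-joining tree of panel plus
#' placeable queries is written in newick.
#'
#' @param fasta Input protein FASTA path.
#' @param out_dir Output directory (created if missing).
#' @param panel Optional [reference_panel()].
#' @param config Optional configuration list (see [resolve_config()]).
#' @return Invisibly, a list with the three report data.frames.
#' @export
run_scan <- function(fasta, out_dir, panel = NULL, config = NULL) {
  cfg <- resolve_config(config)
  records <- read_fasta(fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arch_rep <- architecture_report(records, cfg$params)
  mot_rep <- motif_report(records, cfg$params,
                          min_similarity = cfg$min_similarity,
                          max_gap = cfg$max_gap)
  calls <- classify_records(records, panel = panel, params = cfg$params,
                            min_similarity = cfg$min_similarity,
                            max_gap = cfg$max_gap)
  write_tsv(arch_rep, file.path(out_dir, "architecture.tsv"))
  write_tsv(mot_rep, file.path(out_dir, "motifs.tsv"))
  write_tsv(calls, file.path(out_dir, "calls.tsv"))
  eff <- c(unclass(cfg$params), list(min_similarity = cfg$min_similarity,
                                     max_gap = cfg$max_gap))
  writeLines(paste(names(eff), unlist(eff), sep = ": "),
             file.path(out_dir, "config.effective.yaml"))
  if (!is.null(panel)) {
    seqs <- stats::setNames(panel$trimmed, panel$id)
    for (rec in records) {
      arch <- assemble_architecture(find_c2h2_hits(rec, cfg$params),
                                    cfg$params)
      if (!is.null(arch)) seqs[rec$id] <- trim_zf_region(rec, arch)
    }
    if (length(seqs) >= 3L)
      write_newick(nj_tree(distance_matrix(seqs)),
                   file.path(out_dir, "panel_queries.nwk"))
  }
  invisible(list(architecture = arch_rep, motifs = mot_rep, calls = calls))
}

#' Evaluate origin scenarios for a gene family on a species tree
#'
#' @param tree_path Rooted newick file.
#' @param presence_path Two-column presence table (taxon, 0/1).
#' @param origins Candidate origin node labels; default: every labelled
#'   internal node plus the root.
#' @param out Optional TSV output path.
#' @return The ranked scenario data.frame.
#' @export
run_origins <- function(tree_path, presence_path, origins = NULL,
                        out = NULL) {
  tree <- read_newick(tree_path)
  presence <- read_presence_table(presence_path)
  if (is.null(origins)) {
    origins <- "root"
    if (!is.null(tree$node.label))
      origins <- unique(c(origins,
                          tree$node.label[nzchar(tree$node.label)]))
  }
  ranked <- rank_scenarios(tree, presence, origins)
  if (!is.null(out)) write_tsv(ranked, out)
  ranked
}

#' Render a per-record text summary of a scan
#'
#' @param records List of [protein_record()] objects.
#' @param params A [scan_params()] object.
#' @param min_similarity,max_gap See [rule_classify()].
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
render_report <- function(records, params = scan_params(),
                          min_similarity = 70, max_gap = 30L) {
  lines <- character()
  for (rec in records) {
    call <- rule_classify(rec, params, min_similarity, max_gap)
    lines <- c(lines,
               sprintf("== %s (%d aa) -> %s", rec$id, nchar(rec$sequence),
                       call$label),
               sprintf("   %-22s %-18s %s", call$evidence$criterion,
                       call$evidence$value,
                       ifelse(call$evidence$passed, "PASS", "fail")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
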