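# End-to-end orchestration: a run configuration, the pipeline over a set of
# complexes (+ optional sequence collection), and TSV/JSON/Newick report
# writers with provenance.

#' Build a run configuration
#'
#' All policy knobs of the pipeline in one validated list. The configuration
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param threshold interaction distance threshold in Angstrom (default 3.3).
#' @param assembly `"first"` biological assembly or `"asu"`.
#' @param keep_hydrogens include hydrogens in distance work (default `TRUE`).
#' @param rsa_cutoff,rsa_direction surface-residue criterion (default RSA
#'   below 20%).
#' @param denominator region-score normalization (`"determined"` or
#'   `"all"`).
#' @param sweep_lo,sweep_hi,sweep_step threshold-sweep grid.
#' @param seed integer seed for any stochastic step.
#' @return list of class `trna_run_config`.
#' @export
run_config <- function(threshold = 3.3, assembly = c("first", "asu"),
                       keep_hydrogens = TRUE, rsa_cutoff = 0.20,
                       rsa_direction = c("below", "at_or_above"),
                       denominator = c("determined", "all"),
                       sweep_lo = 2.0, sweep_hi = 5.0, sweep_step = 0.1,
                       seed = 1L) {
  cfg <- list(threshold = threshold, assembly = match.arg(assembly),
              keep_hydrogens = keep_hydrogens, rsa_cutoff = rsa_cutoff,
              rsa_direction = match.arg(rsa_direction),
              denominator = match.arg(denominator),
              sweep_lo = sweep_lo, sweep_hi = sweep_hi,
              sweep_step = sweep_step, seed = as.integer(seed))
  stopifnot(cfg$threshold > 0, cfg$rsa_cutoff > 0, cfg$rsa_cutoff < 1)
  class(cfg) <- "trna_run_config"
  cfg
}

#' @rdname run_config
#' @param config a `trna_run_config`.
#' @param file JSON path.
#' @export
write_run_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  do.call(run_config, jsonlite::read_json(file, simplifyVector = TRUE))
}

#' Run the full interface + conservation pipeline
#'
#' For every input complex: parse (or accept a parsed model), apply the
#' assembly policy, compute the set-distance matrix, contacts, the
#' threshold sweep, the per-position distance profile and the entry
#' summary; then assemble the region score matrix across complexes, the
#' correlation-distance matrix and the complete-linkage dendrogram. When a
#' tRNA record collection is supplied, per-isoacceptor entropy profiles,
#' frequency tables and region conservation summaries are added. The run is
#' deterministic given the configuration and inputs.
#'
#' @param complexes named list; each element is either a path to a PDB
#'   file, a `trna_complex`, or a list with elements `model` (or `path`)
#'   and optionally `assignment` (crystal Sprinzl assignment with `seq_id`
#'   and `label`; identity assignment over the crystal residues is used
#'   when absent) and `metadata` (one-row tibble).
#' @param records optional tRNA record tibble for the conservation arm
#'   (see [filter_records()]); must carry `assignment` list-column or `ss`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every table is written
#'   (TSV with `#` provenance headers, dendrogram as Newick, provenance as
#'   JSON).
#' @param compute_rsa_profiles compute per-entry RSA (off by default: sphere
#'   sampling over large enzymes is the slowest step).
#' @return list of class `trna_run`: per-entry results (`contacts`,
#'   `profiles`, `sweeps`, `summaries`, `rsa`), cross-entry results
#'   (`region_matrix`, `dist_matrix`, `clustering`), conservation results
#'   (`entropy`, `frequencies`, `region_conservation`), and `provenance`.
#' @export
run_pipeline <- function(complexes, records = NULL, config = run_config(),
                         out_dir = NULL, compute_rsa_profiles = FALSE) {
  stopifnot(inherits(config, "trna_run_config"))
  if (is.null(names(complexes)) || any(names(complexes) == "")) {
    rlang::abort("`complexes` must be a fully named list")
  }
  per <- purrr::imap(complexes, function(cx, id) {
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) rlang::abort(
        sprintf("stage %s failed for %s: %s", what, id, conditionMessage(e)),
        parent = e))
    }
    model <- step("parse", resolve_model(cx, id, config))
    sdm <- step("distances", set_distance_matrix(model))
    contacts <- step("contacts",
                     find_contacts(model, config$threshold, sdm = sdm))
    sweep <- step("sweep", threshold_sweep(
      model, config$sweep_lo, config$sweep_hi, config$sweep_step, sdm = sdm))
    assignment <- resolve_assignment(cx, sdm)
    profile <- step("profile", distance_profile(
      model, assignment, config$threshold, sdm = sdm))
    rsa <- NULL
    if (compute_rsa_profiles) rsa <- step("rsa", compute_rsa(model))
    summary <- step("summary", interface_summary(
      model, contacts, rsa = rsa, surface_cutoff = config$rsa_cutoff,
      surface_direction = config$rsa_direction))
    summary$entry_id <- id
    scores <- step("region_scores",
                   region_scores(profile, denominator = config$denominator))
    list(model = model, contacts = contacts, sweep = sweep,
         profile = profile, rsa = rsa, summary = summary, scores = scores,
         metadata = if (is.list(cx) && !inherits(cx, "trna_complex"))
           cx$metadata else NULL)
  })

  metadata <- purrr::imap(per, function(p, id) {
    if (!is.null(p$metadata)) dplyr::mutate(p$metadata, complex_id = id)
  }) |> dplyr::bind_rows()
  region_matrix <- region_score_matrix(
    purrr::map(per, "scores"),
    metadata = if (nrow(metadata)) metadata else NULL)
  dist_matrix <- NULL
  clustering <- NULL
  if (length(per) >= 2) {
    dist_matrix <- tryCatch(correlation_distance_matrix(region_matrix),
                            error = function(e) NULL)
    if (!is.null(dist_matrix) && nrow(dist_matrix) >= 2) {
      clustering <- cluster_complexes(dist_matrix)
    }
  }

  entropy <- frequencies <- conservation_summary <- NULL
  if (!is.null(records)) {
    records <- filter_records(records)
    groups <- unique(records$isoacceptor)
    entropy <- purrr::map(
      setNames(groups, groups),
      function(g) conservation_profile(records, group = g))
    frequencies <- purrr::map(
      setNames(groups, groups),
      function(g) frequency_table(records, group = g))
    conservation_summary <- purrr::imap(entropy, function(e, g) {
      dplyr::mutate(region_conservation(e), isoacceptor = g)
    }) |> dplyr::bind_rows()
  }

  provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_complexes = length(per),
    n_records = if (is.null(records)) 0L else nrow(records),
    input_checksums = purrr::imap_chr(per, function(p, id)
      rlang::hash(p$model$atoms)))

  out <- structure(
    list(contacts = purrr::map(per, "contacts"),
         sweeps = purrr::map(per, "sweep"),
         profiles = purrr::map(per, "profile"),
         rsa = purrr::map(per, "rsa"),
         summaries = dplyr::bind_rows(purrr::map(per, "summary")),
         region_matrix = region_matrix,
         dist_matrix = dist_matrix,
         clustering = clustering,
         entropy = entropy,
         frequencies = frequencies,
         region_conservation = conservation_summary,
         provenance = provenance),
    class = "trna_run")
  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  out
}

#' @noRd
resolve_model <- function(cx, id, config) {
  if (inherits(cx, "trna_complex")) return(cx)
  if (is.character(cx)) {
    return(read_trna_complex(cx, assembly = config$assembly,
                             keep_hydrogens = config$keep_hydrogens,
                             entry_id = id))
  }
  if (!is.null(cx$model)) return(cx$model)
  if (!is.null(cx$path)) {
    return(read_trna_complex(cx$path, assembly = config$assembly,
                             keep_hydrogens = config$keep_hydrogens,
                             entry_id = id))
  }
  rlang::abort("cannot resolve a complex from the given input")
}

#' @noRd
resolve_assignment <- function(cx, sdm) {
  if (is.list(cx) && !inherits(cx, "trna_complex") &&
      !is.null(cx$assignment)) {
    return(cx$assignment)
  }
  # identity assignment: crystal residues in order, labels 1..n
  tibble::tibble(seq_id = sdm$rib$seq_id,
                 label = as.character(seq_len(nrow(sdm$rib))))
}

#' Write the report bundle of a pipeline run
#'
#' TSV tables with a single header line preceded by `#` provenance
#' metadata (`NA` marks undetermined values), the dendrogram as Newick, and
#' the provenance block as JSON.
#'
#' @param run a `trna_run`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- run$provenance$config_hash
  w <- function(tbl, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# trnasurf run, config_hash=%s", hash), con)
    close(con)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     na = "NA")
  }
  contacts <- purrr::imap(run$contacts, function(x, id)
    dplyr::mutate(x, complex_id = id,
                  distance = round(.data$distance, 3))) |>
    dplyr::bind_rows()
  w(contacts, "contacts.tsv")
  profiles <- purrr::imap(run$profiles, function(x, id)
    dplyr::mutate(tibble::as_tibble(x), complex_id = id)) |>
    dplyr::bind_rows()
  w(profiles, "profiles.tsv")
  sweeps <- purrr::imap(run$sweeps, function(x, id)
    dplyr::mutate(x, complex_id = id)) |> dplyr::bind_rows()
  w(sweeps, "sweeps.tsv")
  w(run$summaries, "summary.tsv")
  w(tibble::as_tibble(run$region_matrix), "region_matrix.tsv")
  if (!is.null(run$dist_matrix)) {
    dm <- tibble::as_tibble(run$dist_matrix, rownames = "complex_id")
    w(dm, "distance_matrix.tsv")
  }
  if (!is.null(run$clustering)) {
    cluster_newick(run$clustering, file.path(out_dir, "dendrogram.nwk"))
  }
  if (!is.null(run$entropy)) {
    ent <- purrr::imap(run$entropy, function(x, g)
      dplyr::mutate(tibble::as_tibble(x), isoacceptor = g)) |>
      dplyr::bind_rows()
    w(ent, "entropy.tsv")
    freq <- purrr::imap(run$frequencies, function(x, g)
      dplyr::mutate(x, isoacceptor = g)) |> dplyr::bind_rows()
    w(freq, "frequencies.tsv")
    w(run$region_conservation, "region_conservation.tsv")
  }
  jsonlite::write_json(run$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.trna_run <- function(x, ...) {
  cat("<trna_run> ", length(x$contacts), " complex(es)",
      if (!is.null(x$entropy))
        paste0(", ", length(x$entropy), " isoacceptor group(s)"),
      "\n", sep = "")
  cat("  config hash: ", x$provenance$config_hash, "\n", sep = "")
  invisible(x)
}
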