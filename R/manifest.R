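# Study manifest: scorer roster with roles, per-recording files and lights
# window metadata.

#' Read a study manifest
#'
#' The manifest is a YAML (or JSON) file describing one validation study:
#' \preformatted{
#' study_id: example
#' scorers:
#'   - {id: machine, role: automatic}
#'   - {id: tech1, role: manual}
#' recordings:
#'   - id: rec01
#'     lights_off: "22:14:30"
#'     lights_on: "05:40:00"
#'     files: {machine: rec01_machine.csv, tech1: rec01_tech1.csv}
#' }
#' File paths are resolved relative to the manifest's directory. Roles must
#' include exactly one `automatic` scorer and at least two `manual`
#' scorers; one `clinical` scorer is optional.
#'
#' @param path Path to the manifest file.
#' @return A validated `study_manifest` list with fields `study_id`,
#'   `scorers` (data frame `id`, `role`), `recordings`, and `dir`.
#' @export
read_study_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scorers) || is.null(raw$recordings)) {
    stop("manifest must contain 'scorers' and 'recordings'", call. = FALSE)
  }
  scorers <- data.frame(
    id = vapply(raw$scorers, function(s) as.character(s$id), character(1)),
    role = vapply(raw$scorers, function(s) as.character(s$role),
                  character(1)),
    stringsAsFactors = FALSE
  )
  bad_roles <- setdiff(scorers$role, c("automatic", "manual", "clinical"))
  if (length(bad_roles) > 0L) {
    stop(sprintf("unknown scorer role(s): %s",
                 paste(bad_roles, collapse = ", ")), call. = FALSE)
  }
  if (sum(scorers$role == "automatic") != 1L) {
    stop("manifest must name exactly one automatic scorer", call. = FALSE)
  }
  if (sum(scorers$role == "manual") < 2L) {
    stop("manifest must name at least two manual scorers", call. = FALSE)
  }
  if (sum(scorers$role == "clinical") > 1L) {
    stop("at most one clinical scorer is supported", call. = FALSE)
  }
  if (anyDuplicated(scorers$id)) {
    stop("duplicate scorer ids in manifest", call. = FALSE)
  }
  for (rec in raw$recordings) {
    if (is.null(rec$id) || is.null(rec$files)) {
      stop("every recording needs an 'id' and a 'files' map", call. = FALSE)
    }
    missing <- setdiff(scorers$id, names(rec$files))
    if (length(missing) > 0L) {
      stop(sprintf("recording %s: missing file for scorer(s) %s",
                   rec$id, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(study_id = if (is.null(raw$study_id)) "study" else raw$study_id,
         seed = raw$seed,
         scorers = scorers,
         recordings = raw$recordings,
         dir = dirname(normalizePath(path))),
    class = "study_manifest"
  )
}

#' Load all hypnograms referenced by a study manifest
#'
#' @param manifest A `study_manifest` (from [read_study_manifest()]) or a
#'   path to one.
#' @return List of class `study_data`: per recording, a named list of
#'   [hypnogram()] objects; `scorers` roster attached as an attribute.
#' @export
load_study <- function(manifest) {
  if (is.character(manifest)) manifest <- read_study_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  recs <- lapply(manifest$recordings, function(rec) {
    hyps <- lapply(manifest$scorers$id, function(id) {
      read_hypnogram(file.path(manifest$dir, rec$files[[id]]),
                     recording_id = rec$id, scorer_id = id,
                     lights_off = rec$lights_off,
                     lights_on = rec$lights_on)
    })
    names(hyps) <- manifest$scorers$id
    hyps
  })
  names(recs) <- vapply(manifest$recordings, `[[`, character(1), "id")
  structure(recs, class = "study_data",
            scorers = manifest$scorers, study_id = manifest$study_id)
}
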