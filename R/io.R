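# Configuration files, CSV/JSON run outputs, and deterministic tiny
# fixtures for the equilibrium oracle tests.

config_fields <- function(constructor) setdiff(names(formals(constructor)), "")

config_from_list <- function(lst, game = NULL) {
  if (is.null(game)) game <- lst$game %||% "blossom"
  lst$game <- NULL
  constructor <- switch(game,
    blossom = game_config,
    bats = bat_config,
    stop(sprintf("unknown game '%s' (expected 'blossom' or 'bats')", game),
         call. = FALSE))
  known <- names(formals(constructor))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(constructor, lst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a game configuration from a YAML or JSON file
#'
#' The file holds the constructor arguments of [game_config()] or
#' [bat_config()] plus an optional `game` key (`"blossom"`, the default, or
#' `"bats"`).  Missing keys take the constructor defaults — an empty
#' blossom file yields the reference conditions (2000 players, 19 days,
#' `z = 0.1`, `p = 0.5`, `L = 0.5`, 100 seasons) — and unknown keys are
#' rejected, as are constraint violations.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `blossom_config` or `bat_config`.
#' @seealso [save_config()] for the round-trip writer.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported configuration format '.%s' (use YAML or JSON)",
                 ext), call. = FALSE))
  if (is.null(lst)) lst <- list()
  config_from_list(lst)
}

#' Save a game configuration
#'
#' Writes a configuration so that [load_config()] recovers an identical
#' object.
#'
#' @param cfg A `blossom_config` or `bat_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst <- c(list(game = if (inherits(cfg, "bat_config")) "bats" else "blossom"),
           lst)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop(sprintf("unsupported configuration format '.%s' (use YAML or JSON)",
                 ext), call. = FALSE))
  invisible(path)
}

seasons_frame <- function(result) {
  n_seasons <- length(result$records)
  n_days <- ncol(result$attendance)
  day_rows <- data.frame(
    season = rep(seq_len(n_seasons), each = n_days),
    day = rep(as.character(seq_len(n_days)), times = n_seasons),
    attendance = as.integer(t(result$attendance)),
    mean_utility = as.numeric(t(vapply(result$records,
      function(r) r$mean_utility_by_day, numeric(n_days))))
  )
  home_rows <- data.frame(
    season = seq_len(n_seasons),
    day = "home",
    attendance = vapply(result$records, function(r) r$home_count, integer(1)),
    mean_utility = 0
  )
  out <- rbind(day_rows, home_rows)
  out[order(out$season), ]
}

#' Write a run to disk
#'
#' Emits `seasons.csv` (columns `season`, `day` — a day index or `"home"` —,
#' `attendance`, `mean_utility`), `players_final.csv` (`id`, `m`, `p`,
#' `choice`, `last_utility`, plus `type` for bat runs), `summary.json`
#' (seed, configuration echo, and the [diagnose()] report), `slot_types.csv`
#' (`day`, `slot`, `type`, `count`) for bat runs, and `manifest.json`
#' listing every file written.  Identical runs produce byte-identical CSV
#' files.
#'
#' @param result A `tpg_run`.
#' @param outdir Output directory (created if needed).
#' @param window Diagnostic window passed to [diagnose()].
#' @return The run manifest (a list), invisibly.
#' @export
write_run <- function(result, outdir, window = 20L) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop(sprintf("cannot create output directory: %s", outdir), call. = FALSE)
  files <- character()
  emit <- function(name) {
    files[[length(files) + 1L]] <<- file.path(outdir, name)
    file.path(outdir, name)
  }

  utils::write.csv(seasons_frame(result), emit("seasons.csv"),
                   row.names = FALSE, quote = FALSE)

  finals <- result$final_players
  keep <- intersect(c("id", "type", "m", "p", "choice", "last_utility"),
                    names(finals))
  utils::write.csv(finals[keep], emit("players_final.csv"),
                   row.names = FALSE, quote = FALSE)

  n_seasons <- length(result$records)
  report <- if (n_seasons > 1L)
    diagnose(result, window = min(window, n_seasons - 1L)) else NULL
  summary <- list(
    seed = result$config$seed,
    kind = result$kind,
    config = c(list(game = if (result$kind == "bats") "bats" else "blossom"),
               unclass(result$config)),
    n_seasons = n_seasons,
    convergence = if (!is.null(report)) unclass(report)
  )
  jsonlite::write_json(summary, emit("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (result$kind == "bats") {
    dims <- dim(result$slot_types)
    st <- data.frame(
      day = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
      slot = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
      type = rep(seq_len(dims[3]), each = dims[1] * dims[2]),
      count = as.integer(result$slot_types))
    st <- st[order(st$day, st$slot, st$type), ]
    utils::write.csv(st, emit("slot_types.csv"), row.names = FALSE,
                     quote = FALSE)
  }

  manifest <- list(
    config = summary$config,
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("tpgsim")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = unlist(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic tiny game fixtures
#'
#' Named, fully deterministic instances small enough for the exhaustive
#' equilibrium oracle:
#' \describe{
#'   \item{`"lone"`}{one player on the default 19-day bloom.}
#'   \item{`"tiny-ne"`}{six players with distinct preferences on a 3-day
#'     bloom with `z = 1`, tuned so capacity binds and the greedy
#'     equilibrium sends one player home (`4^6 = 4096` assignments).}
#'   \item{`"boundary"`}{four unit-preference players on a flat 2-day
#'     bloom with `z = 0.5`: a balanced split puts everyone exactly at the
#'     success threshold.}
#' }
#'
#' @param name Fixture name.
#' @return A list with `players` (data frame `id`, `m`), `bloom`, and `cfg`.
#' @export
make_fixture <- function(name) {
  switch(name,
    "lone" = list(
      players = data.frame(id = 1L, m = 2),
      bloom = default_bloom(19L),
      cfg = game_config(n_players = 1L, n_days = 19L, z = 0.1, seed = 1L)),
    "tiny-ne" = list(
      players = data.frame(id = 1:6, m = c(3, 2.4, 2, 1.5, 1.2, 1)),
      bloom = bloom_profile(c(1, 2.5, 1)),
      cfg = game_config(n_players = 6L, n_days = 3L, z = 1, seed = 1L)),
    "boundary" = list(
      players = data.frame(id = 1:4, m = c(1, 1, 1, 1)),
      bloom = bloom_profile(c(1, 1)),
      cfg = game_config(n_players = 4L, n_days = 2L, z = 0.5, seed = 1L)),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE))
}
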