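#' Read a simulation configuration file
#'
#' Parses a flat `key = value` text file into the three simulation
#' parameter objects. Unknown keys raise an error; omitted keys keep the
#' package defaults. `copies_prob` is written as `count:weight` pairs
#' separated by commas (e.g. `1:0.2,2:0.35,3:0.3,4:0.15`).
#'
#' @param path path to the configuration file. Lines starting with `#` and
#'   blank lines are ignored.
#' @return list with `layout` ([read_layout()]), `errmodel`
#'   ([error_model()]), `design` ([population_design()]) and `seed`
#'   (integer or `NULL`).
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "example_config.txt",
#'                                    package = "ampliMHC"))
#' cfg$errmodel$substitution_rate
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1])
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
  }
  chr <- function(key, default) cfg[[key]] %||% default
  layout_def <- read_layout()
  err_def <- error_model()
  des_def <- population_design()
  copies <- if (is.null(cfg$copies_prob)) {
    des_def$copies_prob
  } else {
    parts <- strsplit(strsplit(cfg$copies_prob, ",")[[1]], ":")
    if (any(lengths(parts) != 2)) stop("malformed copies_prob")
    stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                    trimws(vapply(parts, `[`, character(1), 1)))
  }
  known <- c("adaptor_fwd", "adaptor_rev", "mid_length", "primer_fwd",
             "primer_rev", "substitution_rate", "homopolymer_indel_rate",
             "chimera_rate", "reads_per_replicate", "n_individuals",
             "copies_prob", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) stop("unknown config key: ", unknown[1])
  list(layout = read_layout(adaptor_fwd = chr("adaptor_fwd", layout_def$adaptor_fwd),
                            adaptor_rev = chr("adaptor_rev", layout_def$adaptor_rev),
                            mid_length = num("mid_length", layout_def$mid_length),
                            primer_fwd = chr("primer_fwd", layout_def$primer_fwd),
                            primer_rev = chr("primer_rev", layout_def$primer_rev)),
       errmodel = error_model(substitution_rate = num("substitution_rate", err_def$substitution_rate),
                              homopolymer_indel_rate = num("homopolymer_indel_rate", err_def$homopolymer_indel_rate),
                              chimera_rate = num("chimera_rate", err_def$chimera_rate),
                              reads_per_replicate = num("reads_per_replicate", err_def$reads_per_replicate)),
       design = population_design(n_individuals = num("n_individuals", des_def$n_individuals),
                                  copies_prob = copies),
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}
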