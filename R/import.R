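# MAT-file importer for the deposited behavioral dataset.
#
# R in this toolchain has no MAT reader, so the importer shells out to
# the system `python` (scipy.io.loadmat) to convert the file to JSON
# and then maps variables explicitly. The internal variable names of
# the deposited file are not documented, so the mapping is an argument
# the user can edit; nothing is guessed silently.

mat_to_json_py <- "
import json, sys
import numpy as np
import scipy.io as sio
mat = sio.loadmat(sys.argv[1], squeeze_me=True)
out = {}
for k, v in mat.items():
    if k.startswith('__'):
        continue
    if isinstance(v, np.ndarray):
        out[k] = v.tolist()
    elif isinstance(v, (int, float, str, list)):
        out[k] = v
json.dump(out, open(sys.argv[2], 'w'))
"

#' Import a deposited MATLAB dataset
#'
#' Converts a MAT-file holding the participants' choices, the stimulus
#' network, and the personality survey into the package's native types.
#' Variables are located by an explicit `mapping` (no silent guessing):
#' `choices` must name a participants x 2 matrix of selected node ids,
#' `edges` an edge list (E x 2), `personality` a participants x 5 matrix
#' in the order openness, conscientiousness, extraversion,
#' agreeableness, neuroticism, and (optionally) `n_nodes` a scalar node
#' count. Node ids are converted from `index_base` (1 for MATLAB) to
#' the package's 0-based convention. Missing variables raise an error
#' listing what the file actually contains.
#'
#' @param path MAT-file path.
#' @param mapping named list with entries `choices`, `edges`,
#'   `personality`, and optionally `n_nodes`, giving the MAT variable
#'   names.
#' @param index_base index origin of node ids in the file.
#' @param python python executable with scipy available.
#' @return list with `graph` (igraph), `records` (choice table),
#'   `personality` (trait table), and `field_map` (the mapping report).
#' @export
import_study_data <- function(path,
                              mapping = list(choices = "choices",
                                             edges = "edges",
                                             personality = "personality",
                                             n_nodes = "n_nodes"),
                              index_base = 1L,
                              python = "python") {
  if (!file.exists(path)) stop("no such file: ", path)
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path))
  script <- tempfile(fileext = ".py")
  writeLines(mat_to_json_py, script)
  on.exit(unlink(script), add = TRUE)
  res <- suppressWarnings(
    system2(python, c(script, shQuote(path), shQuote(json_path)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(json_path)) {
    stop("could not read MAT file ", path, ": ",
         paste(res, collapse = "\n"))
  }
  vars <- jsonlite::read_json(json_path, simplifyVector = TRUE)

  required <- c("choices", "edges", "personality")
  missing <- vapply(required, function(k) {
    is.null(mapping[[k]]) || !mapping[[k]] %in% names(vars)
  }, logical(1))
  if (any(missing)) {
    stop("MAT file lacks mapped variable(s) ",
         paste(unlist(mapping[required[missing]]), collapse = ", "),
         "; file contains: ", paste(names(vars), collapse = ", "))
  }

  as_mat <- function(x, ncol_need, what) {
    x <- as.matrix(x)
    if (ncol(x) != ncol_need) {
      stop(what, " must have ", ncol_need, " columns, found ", ncol(x))
    }
    x
  }
  choices <- as_mat(vars[[mapping$choices]], 2L, "choices")
  edges <- as_mat(vars[[mapping$edges]], 2L, "edges")
  pers <- as_mat(vars[[mapping$personality]], 5L, "personality")
  if (nrow(pers) != nrow(choices)) {
    stop("personality rows (", nrow(pers), ") do not match choices rows (",
         nrow(choices), ")")
  }

  shift <- as.integer(index_base)
  edges0 <- edges - shift
  choices0 <- choices - shift
  n_nodes <- if (!is.null(mapping$n_nodes) &&
                 mapping$n_nodes %in% names(vars)) {
    as.integer(vars[[mapping$n_nodes]])
  } else {
    max(edges0) + 1L
  }
  if (any(edges0 < 0L) || any(edges0 >= n_nodes)) {
    stop("edge node ids fall outside 0..", n_nodes - 1L,
         " after index-base conversion; check index_base")
  }
  if (any(choices0 < 0L) || any(choices0 >= n_nodes)) {
    stop("choice node ids fall outside the graph; check index_base")
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, t(edges0 + 1L))
  records <- data.frame(participant_id = seq_len(nrow(choices0)),
                        first_choice = as.integer(choices0[, 1L]),
                        second_choice = as.integer(choices0[, 2L]))
  validate_records(records, g)
  personality <- data.frame(participant_id = records$participant_id,
                            openness = pers[, 1L],
                            conscientiousness = pers[, 2L],
                            extraversion = pers[, 3L],
                            agreeableness = pers[, 4L],
                            neuroticism = pers[, 5L])
  list(graph = g, records = records, personality = personality,
       field_map = list(mapping = mapping, index_base = index_base,
                        n_nodes = n_nodes,
                        variables_in_file = names(vars)))
}
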