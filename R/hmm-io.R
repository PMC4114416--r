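# JSON serialisation of models and networks. The schema is versioned and
# round-trips losslessly (full double precision via digits = NA).

num_row <- function(row) {
  vapply(row, function(v) if (is.null(v)) -Inf else as.numeric(v), numeric(1))
}

hmmToList <- function(model) {
  lt <- model@logTrans
  lt[!is.finite(lt)] <- NA_real_   # -Inf encoded as JSON null
  list(label = model@label,
       n_states = model@nStates,
       log_transitions = apply(lt, 1L, as.numeric, simplify = FALSE),
       emissions = lapply(model@emissions, function(e)
         list(weights = as.numeric(e$weights),
              means = apply(e$means, 1L, as.numeric, simplify = FALSE),
              variances = apply(e$variances, 1L, as.numeric,
                                simplify = FALSE))))
}

hmmFromList <- function(x) {
  S <- as.integer(x$n_states)
  lt <- do.call(rbind, lapply(x$log_transitions, num_row))
  lt[is.na(lt)] <- -Inf
  new("Hmm", label = x$label, nStates = S, logTrans = lt,
      emissions = lapply(x$emissions, function(e)
        list(weights = num_row(e$weights),
             means = do.call(rbind, lapply(e$means, num_row)),
             variances = do.call(rbind, lapply(e$variances, num_row)))))
}

#' Save a recognition network as JSON
#'
#' Writes a versioned JSON document (label, topology, log transitions,
#' mixture parameters per state, keyword label, loop penalty). Doubles are
#' written at full precision so save/load round-trips are lossless; -Inf log
#' probabilities are encoded as nulls.
#'
#' @param net a [RecognitionNetwork-class].
#' @param path output path.
#' @export
saveNetwork <- function(net, path) {
  doc <- list(format = "coughSpot-network", version = 1L,
              keyword = net@keyword, loop_penalty = net@loopPenalty,
              models = lapply(net@models, hmmToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a recognition network saved by [saveNetwork()]
#' @param path path to the JSON file.
#' @return A [RecognitionNetwork-class].
#' @export
loadNetwork <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "coughSpot-network"))
    stop("not a coughSpot network file: ", path)
  new("RecognitionNetwork",
      models = lapply(doc$models, hmmFromList),
      keyword = doc$keyword,
      loopPenalty = as.numeric(doc$loop_penalty))
}
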