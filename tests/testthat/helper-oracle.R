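# Independent flow-accounting oracle for one annual cycle: enumerates every
# transition edge cell by cell with scalar loops and an explicit ledger of
# flows, deliberately sharing no code with step_cycle()'s vectorised path.
oracle_step <- function(state, rates, projection_next, ageing = TRUE) {
  nb <- adcohort::age_bands()
  n <- nrow(nb)
  states <- c("unimpaired", "mci", "mild", "moderate", "severe")
  cur <- state$counts
  nxt <- array(0, dim = dim(cur), dimnames = dimnames(cur))

  edges <- list(
    list(from = "mci", to = "mild", p = rates$mci_mild),
    list(from = "mild", to = "moderate", p = rates$mild_moderate),
    list(from = "moderate", to = "severe", p = rates$moderate_severe),
    list(from = "moderate", to = "mild", p = rates$moderate_mild),
    list(from = "severe", to = "moderate", p = rates$severe_moderate),
    list(from = "mci", to = "dead", p = rates$mort_mci),
    list(from = "mild", to = "dead", p = rates$mort_mild),
    list(from = "moderate", to = "dead", p = rates$mort_moderate),
    list(from = "severe", to = "dead", p = rates$mort_severe))

  for (b in seq_len(n)) {
    for (s in 1:2) {
      occ <- cur[, b, s]
      names(occ) <- states
      ledger <- list()
      for (e in edges) {
        flow <- occ[[e$from]] * e$p
        ledger[[length(ledger) + 1L]] <- c(from = e$from, to = e$to,
                                           flow = flow)
      }
      res <- occ
      for (l in ledger) {
        res[[l[["from"]]]] <- res[[l[["from"]]]] - as.numeric(l[["flow"]])
        if (l[["to"]] != "dead")
          res[[l[["to"]]]] <- res[[l[["to"]]]] + as.numeric(l[["flow"]])
      }
      # incidence out of unimpaired into MCI
      inc <- cur["unimpaired", b, s] * rates$incidence[[b]]
      res[["mci"]] <- res[["mci"]] + inc
      res[["unimpaired"]] <- res[["unimpaired"]] - inc
      for (st in states) nxt[st, b, s] <- res[[st]]
    }
  }

  if (ageing) {
    aged <- nxt
    for (st in c("mci", "mild", "moderate", "severe")) {
      for (s in 1:2) {
        col <- nxt[st, , s]
        moved <- col / 5
        out <- col - moved
        for (b in seq_len(n - 1L)) out[b + 1L] <- out[b + 1L] + moved[b]
        out[n] <- out[n] + moved[n]
        aged[st, , s] <- out
      }
    }
    nxt <- aged
  }

  for (b in seq_len(n)) {
    for (s in 1:2) {
      resid <- projection_next[b, s] - sum(nxt[2:5, b, s])
      nxt["unimpaired", b, s] <- max(0, resid)
    }
  }
  adcohort::state_vector(state$year + 1L, nxt)
}

# small helper: reference parameters on a tiny synthetic population so the
# heavier property suites stay fast
small_reference <- function(seed = 1L, total = 5e6) {
  reference_parameters(population = synthetic_population_projection(
    synthetic_population_config(total_population = total, seed = seed)))
}
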