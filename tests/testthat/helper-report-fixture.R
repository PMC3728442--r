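# Hand-built three-participant fixture over the abstract domain, used by
# the reporting tests. Plan: X = c01 c02 c07 (availability opportunity at
# c07), Y = c04 c05 c06 (gambler's-fallacy opportunity at c06; all {B}).
fixture_report <- function() {
  kb <- kb4()
  cases <- cases4()
  cases$subdomain[4:6] <- "Y"
  plan <- sequence_plan(list(X = c("c01", "c02", "c07"),
                             Y = c("c04", "c05", "c06")))
  sat <- function(dx) ev_stream(paste0("H:", dx), paste0("D:", dx), "CLOSE")
  ok <- function(dx) ev_stream(paste0("F:f1"), paste0("H:", dx),
                               paste0("D:", dx), "H:C", "CLOSE")
  streams <- list(
    # p1 completes all six; satisfices three times; availability-errs on c07
    p1 = list(c01 = sat("C"), c02 = sat("C"),
              c07 = ev_stream("H:A", "D:A", "H:B", "CLOSE"),  # echo: avail
              c04 = ok("B"), c05 = ok("B"), c06 = sat("D")),
    # p2 completes five of six (c02 left open): c07 loses its denominator
    p2 = list(c01 = ok("A"),
              c02 = ev_stream("F:f1", "H:A", "D:A"),          # not closed
              c07 = ev_stream("H:A", "D:A", "H:B", "CLOSE"),
              c04 = ok("B"), c05 = ok("B"), c06 = ok("B")),
    # p3 completes only the Y arm
    p3 = list(c04 = ok("B"), c05 = ok("D"), c06 = ok("B"))
  )
  sessions <- do.call(c, lapply(names(streams), function(p)
    unclass(mk_sessions(streams[[p]], participant = p,
                        level = match(p, names(streams))))))
  rep <- detect_all(structure(sessions, class = "dxbias_sessions"),
                    kb, plan, cases)
  list(rep = rep, plan = plan, cases = cases)
}
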