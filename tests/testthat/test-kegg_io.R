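# Synthetic KGML fixtures written at test time: three tiny maps whose
# merged union is known by construction.

kgml_text <- function(map, entries, reactions) {
  paste0(
    '<?xml version="1.0"?>\n',
    sprintf('<pathway name="path:%s" org="ko" number="1">\n', map),
    paste(entries, collapse = "\n"), "\n",
    paste(reactions, collapse = "\n"), "\n",
    "</pathway>\n"
  )
}

cpd_entry <- function(id, cnum) {
  sprintf('<entry id="%d" name="cpd:%s" type="compound"/>', id, cnum)
}

rxn_elem <- function(rnum, subs, prods, type = "irreversible") {
  paste0(
    sprintf('<reaction id="9%s" name="rn:%s" type="%s">\n', sub("^R", "", rnum), rnum, type),
    paste(sprintf('  <substrate id="1" name="cpd:%s"/>', subs), collapse = "\n"), "\n",
    paste(sprintf('  <product id="2" name="cpd:%s"/>', prods), collapse = "\n"), "\n",
    "</reaction>"
  )
}

write_map <- function(path, map, entries, reactions) {
  writeLines(kgml_text(map, entries, reactions), path)
  path
}

local_three_maps <- function(env = parent.frame()) {
  m1 <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  m2 <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  m3 <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  # map 1: C00001 -> R00001 -> C00002 (irreversible)
  write_map(m1, "ko00901",
            c(cpd_entry(1L, "C00001"), cpd_entry(2L, "C00002")),
            rxn_elem("R00001", "C00001", "C00002"))
  # map 2: C00002 <-> C00003 (reversible), sharing C00002 with map 1
  write_map(m2, "ko00902",
            c(cpd_entry(1L, "C00002"), cpd_entry(2L, "C00003")),
            rxn_elem("R00002", "C00002", "C00003", type = "reversible"))
  # map 3: C00003 -> R00003 -> C00004
  write_map(m3, "ko00903",
            c(cpd_entry(1L, "C00003"), cpd_entry(2L, "C00004")),
            rxn_elem("R00003", "C00003", "C00004"))
  list(m1 = m1, m2 = m2, m3 = m3)
}

test_that("minimal KGML maps parse with direction and id hygiene", {
  maps <- local_three_maps()
  frag <- parse_kgml(maps$m1)
  expect_s3_class(frag, "pathway_fragment")
  expect_identical(frag$map_id, "ko00901")
  expect_identical(frag$compounds, c("C00001", "C00002"))
  expect_length(frag$reactions, 1L)
  expect_identical(frag$reactions[[1L]]$id, "R00001")
  expect_false(frag$reactions[[1L]]$reversible)
  expect_true(parse_kgml(maps$m2)$reactions[[1L]]$reversible)

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway name='path:ko1'><entry", bad)
  expect_error(parse_kgml(bad), "malformed KGML")

  empty <- withr::local_tempfile(fileext = ".xml")
  write_map(empty, "ko00999", cpd_entry(1L, "C00009"), character())
  expect_warning(frag0 <- parse_kgml(empty), "no reaction elements")
  expect_length(frag0$reactions, 0L)
})

test_that("merging maps unions fragments, marks hosts, and decomposes P/Q", {
  maps <- local_three_maps()
  frags <- lapply(maps, parse_kgml)
  net <- merge_maps(reference = frags, host = frags[1L],
                    sources = "C00001", target = "C00004")
  # R00002 is reversible: P/Q halves; others unchanged
  expect_setequal(net$reactions, c("R00001", "P00002", "Q00002", "R00003"))
  expect_identical(net$compounds, sprintf("C%05d", 1:4))
  # shared compound C00002 exists once, with merged edges
  expect_setequal(net$producers$C00002, c("R00001", "Q00002"))
  # host comes from map 1 only
  expect_identical(additional_reactions(net), c("P00002", "Q00002", "R00003"))
  sol <- solve_mri(net)
  expect_identical(sol$objective, 2L)   # one pair decision + R00003

  # host = reference: nothing to insert
  net_all <- merge_maps(reference = frags, host = frags,
                        sources = "C00001", target = "C00004")
  expect_length(additional_reactions(net_all), 0L)
  expect_identical(solve_mri(net_all)$status, "trivial")

  expect_error(merge_maps(frags, frags[1L], sources = "C99999", target = "C00004"),
               "source compounds absent")
  expect_error(merge_maps(frags, frags[1L], sources = "C00001", target = "C99999"),
               "absent from the merged network")
})

test_that("fragment merge order does not matter and JSON round-trips", {
  maps <- local_three_maps()
  frags <- lapply(maps, parse_kgml)
  n1 <- merge_maps(frags, frags[1L], sources = "C00001", target = "C00004")
  n2 <- merge_maps(rev(frags), frags[1L], sources = "C00001", target = "C00004")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(n1, f1)
  write_network_json(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_network_json(f1)
  expect_identical(back$edges, n1$edges)
  expect_identical(back$host_nodes, n1$host_nodes)
  # provenance: every reaction traces back to at least one map
  prov <- attr(n1, "provenance")
  expect_true(all(lengths(prov[c("R00001", "R00002", "R00003")]) >= 1L))
})
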