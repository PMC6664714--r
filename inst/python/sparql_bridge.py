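#!/usr/bin/env python3
"""SPARQL execution bridge.

Reads a JSON manifest describing a graph view (default graph and optional
named graphs, all as N-Triples files) and a list of operations, executes
each operation with rdflib, and writes per-operation result files:

  select    -> SPARQL 1.1 JSON results
  ask       -> SPARQL 1.1 JSON results (boolean)
  construct -> N-Triples
  update    -> N-Triples of the updated default graph

Exit codes: 0 all operations executed; 2 a query failed to parse or the
manifest is unusable (details on stderr as JSON).
"""

import json
import sys

import rdflib
from rdflib import ConjunctiveGraph, Graph, URIRef


def build_graph(manifest):
    named = manifest.get("named_graphs") or {}
    if named:
        g = ConjunctiveGraph()
        ctx = g.get_context(URIRef("urn:owlet:default"))
        ctx.parse(manifest["default_graph"], format="nt")
        for iri, path in named.items():
            g.get_context(URIRef(iri)).parse(path, format="nt")
        return g
    g = Graph()
    g.parse(manifest["default_graph"], format="nt")
    return g


def main():
    manifest_path = sys.argv[1]
    with open(manifest_path) as fh:
        manifest = json.load(fh)
    graph = build_graph(manifest)
    for op in manifest["operations"]:
        with open(op["query_file"]) as fh:
            query_text = fh.read()
        try:
            if op["type"] in ("select", "ask"):
                result = graph.query(query_text)
                data = result.serialize(format="json")
                with open(op["out"], "wb") as out:
                    out.write(data)
            elif op["type"] == "construct":
                result = graph.query(query_text)
                out_graph = Graph()
                for triple in result:
                    out_graph.add(triple)
                out_graph.serialize(destination=op["out"], format="nt",
                                    encoding="utf-8")
            elif op["type"] == "update":
                graph.update(query_text)
                target = graph
                if isinstance(graph, ConjunctiveGraph):
                    target = Graph()
                    for triple in graph.triples((None, None, None)):
                        target.add(triple)
                target.serialize(destination=op["out"], format="nt",
                                 encoding="utf-8")
            else:
                raise ValueError("unknown operation type: %s" % op["type"])
        except Exception as exc:  # surface as a structured parse/exec error
            sys.stderr.write(json.dumps(
                {"id": op.get("id"), "error": str(exc)}) + "\n")
            sys.exit(2)
    sys.exit(0)


if __name__ == "__main__":
    main()
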