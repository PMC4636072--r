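#!/usr/bin/env python
"""Execute a DDL file on an in-memory SQLite database and print the catalog.

Output: JSON list of tables (sorted by name), each with columns
(name/type/notnull/pk), non-clustered index column sets (auto indexes and the
primary key excluded), and foreign keys.
"""
import json
import sqlite3
import sys


def main(ddl_path):
    with open(ddl_path, "r", encoding="utf-8") as fh:
        ddl = fh.read()
    con = sqlite3.connect(":memory:")
    con.executescript(ddl)
    cur = con.cursor()
    tables = [r[0] for r in cur.execute(
        "SELECT name FROM sqlite_master WHERE type='table' "
        "AND name NOT LIKE 'sqlite_%' ORDER BY name").fetchall()]
    out = []
    for t in tables:
        cols = [{"name": r[1], "type": r[2], "notnull": bool(r[3]),
                 "pk": bool(r[5])}
                for r in cur.execute(f"PRAGMA table_info({t})").fetchall()]
        idx = []
        for r in cur.execute(f"PRAGMA index_list({t})").fetchall():
            iname, origin = r[1], r[3]
            if origin != "c":   # skip pk/unique auto indexes
                continue
            icols = [x[2] for x in
                     cur.execute(f"PRAGMA index_info({iname})").fetchall()]
            idx.append(",".join(icols))
        fks = [{"column": r[3], "target_table": r[2], "target_column": r[4]}
               for r in cur.execute(f"PRAGMA foreign_key_list({t})").fetchall()]
        fks.sort(key=lambda f: f["column"])
        out.append({"name": t, "columns": cols, "indexes": sorted(idx),
                    "foreign_keys": fks})
    print(json.dumps(out))


if __name__ == "__main__":
    main(sys.argv[1])
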