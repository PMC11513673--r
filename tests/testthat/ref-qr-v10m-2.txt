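% reference module grid: version 10-M byte-mode symbol, mask 3
% produced by an independent third-party encoder (reportlab.graphics.barcode.qrencoder,
% a port of Kazuhiko Arase's QR library) during development; frozen as a plain-text oracle
% payload: 1.1000,0.6000,110.5000,37.8000,0.3300,12.0000,99.9999,0.0001,55.5000,3.1416,2.7183,0.5772
#######.##.####.#..#.#.#...##.#..#.##.....#...##..#######
#.....#.#.#..#......#..###.##.##.#.#.##...#.#..#..#.....#
#.###.#..##...##.#..######.#...#.#..##..###.####..#.###.#
#.###.#.##..#...#...##.#.#.#.######.#...#......#..#.###.#
#.###.#..#..###..##..#.#..#####..###..#.#.#.#..#..#.###.#
#.....#.......#####..#...##...#.#.#...##....#.#...#.....#
#######.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#######
........###.#..#.###..#.#.#...###..#####.#.####.#........
#.##.###.##..##..#...#..#.######.##.....##.#...#..#..#.##
#..##..#.#...###.#.###..###.#.##.#.#......##.#..#....####
..#####.##......###.#..##.....#.##..........###..##.....#
#.#.#..##.#..##..#.#.##...#.#..#.#....##.###......#.#..#.
.#....#.#....####..#.#.##...########..##...##...#.#.##...
..##...#..#........#.#.#..#.##.....###.#..#.....##..##.#.
#.#...#..##.#.##.###...#...#.#..##.###.##...##..##.#.#.#.
.####....###....####.##.#....#.##.###...#.##.#.#....#.##.
#######.##..#####.#.#.##.##..##.#..#.##.....##..#.#......
#.###..#.#....##.......###.#####..##.#.##.....#..#.####..
.####.#..#.#..###..#..#....#..##..#.##...#.....######....
##.##..#.#..##.#..#...#.#.#..#...###.#...#.#.####..##.###
#.######.####...#..#...#..##.#.#...#####...#....#...#..#.
.#..##.###.......####...##.##.#...#..####.#.#.#.#..#..#..
.#..###.#.#..#.....####..#.##...#...#.###.##...#.......#.
.#.....#####..###.###.#..#........####.##..##.#..#.##..##
.###.##.###...#..#..#....###..#.....#..#.##....###.#...##
..#..#.######..#####...#.#..##.##..#..##.#..#..#..##.#.#.
###.#####.#.#...##.######.######.##...#.##.#.########..#.
#.#.#...###..##.#.##.##.#.#...#...##.###.#......#...#.#.#
#..##.#.##.#.##.#.##....###.#.##..##...#####..###.#.#.##.
#.#.#...#.##.######.......#...####.###...####.#.#...##..#
.##.######..#.###..#.#.##.########..###.#.###.#.######...
.......#.##....#####...#..#..####.#...####.##.#####..#..#
.###.##..####.###..####..#.#.#.#..#.....##.#.###..#.####.
.#..#..#.####.#...######..##...#.#.##..#..##.#.#..#.##.#.
..#.#.#.#.########.#...##.####..####.####...#.#.##..#####
.#.#.#.....####..###.#.##.#.#.#.#.#...##...#.#...#.#.###.
.#..###.#..#######.#...####..#....##..##.######....#..#..
...###.##.....#..##..###.##..####..###..##...###.##..#..#
########.......##...#..#.#######...###.#.##.#.#.##...#..#
.##.##.####.#.#...#...#.#..#..####.##.....#.##.###.#..#.#
..##.###...##..####..#.#..#..#..##.#.##..#..##.##.###..#.
#..##...###.#.####..##.###.#.#.#..##.#.##..#..#..#..###..
##.#####..#.#.##.###.#...#.##.#.....##.#.#.....#...#.....
#.#.##.###..##.##..#..#.#.###...###.#.#...##.##....###.##
.#...###.#..###.#..##.####.####.#....#.#..##......##.###.
...##..##.###....###.#..#.##....#.#.#..###....#...##..#.#
#.#..#####.#.##.#.#..#.#.###..##...#...###..#.....##.#..#
#####..#..##.#####..##..###.#.....###..##.....#.#.#.#..#.
......#.....##...#....##..#####.....##.#.##..#.######....
........###.##...#..#.##..#...###..#..##.#.##..##...#..#.
#######.##..##..#..#.##...#.#.##.####.#.##.#.#.##.#.####.
#.....#.#.##....#...#..#..#...#..#..######....###...#.#.#
#.###.#...#.##.....#.##...######....#....###....#####.##.
#.###.#.#.##.#.#####..#....#.####.#.#.#######.##..#.#..#.
#.###.#.#....#...#.#..######...##.##...#..###.#.#.#.###..
#.....#...#####.#....###.....#.#.##...#.##.##....#..##..#
#######.#...#..###.#......##.###........#..#.##..#.#.#...
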