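# nodes: 1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 17 18 19 20 21 22 23 24 25 26 27 28 29 30 31 32 33 34 35 36 37 38 39 40 41 42 43 44 45 46 47 48 49 50 51 52 53 54 55 56 57 58 59 60
1 3
1 4
1 5
1 6
1 7
1 15
1 19
1 29
1 30
1 32
1 53
2 9
2 14
2 15
2 17
2 19
2 23
2 25
2 28
3 5
3 16
3 19
3 22
3 24
3 27
4 9
4 22
4 23
4 25
4 27
5 7
5 16
5 17
5 18
5 21
5 27
5 28
5 29
5 30
5 58
6 8
6 9
6 20
6 25
6 27
6 32
6 39
7 20
7 24
7 25
7 29
7 35
7 40
7 53
7 55
8 15
8 23
8 26
8 29
9 13
9 15
9 16
9 20
9 31
10 12
11 13
11 19
11 23
11 29
12 13
12 15
13 19
13 51
14 19
14 21
14 28
15 19
15 23
15 24
16 17
16 19
16 22
16 24
16 26
16 28
16 29
16 34
16 60
17 20
17 26
17 28
18 19
18 20
18 22
18 24
18 27
18 29
18 40
18 59
19 23
19 58
21 22
21 27
21 29
22 23
22 60
23 25
23 30
24 29
24 36
25 29
25 35
26 27
26 30
27 30
28 30
30 59
31 34
31 37
31 39
31 41
31 44
31 55
32 36
32 49
32 56
32 59
33 35
33 38
33 40
33 41
33 43
33 51
33 54
34 35
34 37
34 43
34 45
34 59
35 41
35 49
35 51
35 52
35 53
35 55
36 39
36 41
36 47
36 48
36 51
36 58
37 38
37 39
37 43
37 44
37 46
37 47
37 49
37 50
37 52
37 54
37 56
37 57
37 59
37 60
38 39
38 41
38 46
38 55
38 60
39 41
39 47
39 48
39 55
39 56
39 57
39 60
40 41
40 48
40 53
40 56
40 57
40 60
41 46
41 47
41 49
41 51
41 54
42 54
42 57
43 44
43 47
43 56
43 60
44 48
44 49
44 54
44 55
44 60
45 46
45 50
45 58
45 59
45 60
46 47
46 51
46 52
46 58
46 59
47 54
47 56
48 49
48 53
48 59
49 52
49 58
50 54
50 60
51 53
51 56
53 56
53 58
53 59
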