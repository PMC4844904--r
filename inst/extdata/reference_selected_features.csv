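test_id,vocal_test,features
1,vowel a,
2,vowel o,24
3,vowel u,
4,number 1,1;2;3;4;5;24
5,number 2,2;9;10
6,number 3,17;19;23;25;26
7,number 4,1;2;3;4;5;10
8,number 5,24
9,number 6,
10,number 7,
11,number 8,9
12,number 9,26
13,number 10,
14,short sentence 1,
15,short sentence 2,25;26
16,short sentence 3,4;10;25;26
17,short sentence 4,1;2;3;4;5;10;26
18,word 1,2
19,word 2,
20,word 3,17;19;23;25
21,word 4,
22,word 5,
23,word 6,
24,word 7,
25,word 8,1;2;3;4;5;6;17;19;23;25
26,word 9,24
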